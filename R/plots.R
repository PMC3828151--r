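# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tract-length histogram on the log-abundance scale
#'
#' Regular bins only (the whole-chromosome bin is annotated in the
#' subtitle); a single migration pulse shows as a straight line, repeated
#' migration as a concave curve.
#'
#' @param object A `tract_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tract_histogram <- function(object, ...) {
  n_bins <- ncol(object$counts) - 1
  mid <- (head(object$bin_edges, -1) + object$bin_edges[-1]) / 2
  tb <- purrr::map_dfr(rownames(object$counts), function(a) {
    tibble::tibble(ancestry = a, length_M = mid,
                   count = object$counts[a, seq_len(n_bins)])
  })
  whole <- rowSums(object$counts[, n_bins + 1, drop = FALSE])
  ggplot2::ggplot(tb[tb$count > 0, ],
                  ggplot2::aes(x = .data$length_M, y = .data$count,
                               colour = .data$ancestry)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "tract length (Morgans)", y = "tract count",
      subtitle = paste0("whole-chromosome tracts: ",
                        paste(sprintf("%s=%.4g", names(whole), whole),
                              collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of ASPCA scores
#'
#' @param object An `aspca_fit`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot of the first two components, coloured by population
#'   and shaped by reference/admixed group.
#' @export
autoplot.aspca_fit <- function(object, components = 1:2, ...) {
  tb <- tidy(object)
  cn <- colnames(object$scores)[components]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data[[cn[1]]], y = .data[[cn[2]]],
                                   colour = .data$population,
                                   shape = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::theme_minimal()
}

#' Bar plot of size-stratified source assignment
#'
#' @param assignment Tibble from [size_stratified_assignment()] (or the
#'   `summary` of an [assignment_summary()]).
#' @return A ggplot of rescaled mean assignment probabilities per source
#'   population and tract-length class, with SEM error bars.
#' @export
plot_assignment <- function(assignment) {
  ggplot2::ggplot(assignment,
                  ggplot2::aes(x = .data$population,
                               y = .data$rescaled_mean,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rescaled_mean - .data$sem,
                   ymax = .data$rescaled_mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::labs(x = "source population",
                  y = "rescaled mean assignment probability") +
    ggplot2::theme_minimal()
}

#' Tile plot of local ancestry calls
#'
#' @param painting An [infer_local_ancestry()] result.
#' @param use Which labels to show: thresholded `"call"` (default, with
#'   "unknown") or `"viterbi"`.
#' @return A ggplot with haplotypes on the y axis and windows on x.
#' @export
plot_painting <- function(painting, use = c("call", "viterbi")) {
  use <- match.arg(use)
  ggplot2::ggplot(painting$calls,
                  ggplot2::aes(x = .data$window, y = .data$hap_id,
                               fill = .data[[use]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "window", y = NULL, fill = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
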