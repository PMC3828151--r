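# Pulse-migration demographic models.
#
# Time is counted in generations before present: the founding event happens
# T1 generations ago and the present-day sample is generation 1, so a
# lineage founded at T1 has passed through T1 - 1 meioses. Pulse times lie
# strictly between 1 and T1. Times may be non-integer; see
# discretize_migration_model() for how fractional times are handled.

#' Construct a pulse-migration model
#'
#' A founding event (time `T1`, ancestry proportions) plus zero or more
#' later migrant pulses. A pulse at time `t` with source `s` and magnitude
#' `m` replaces a fraction `m` of the population with unadmixed `s`
#' chromosomes, `t` generations before present.
#'
#' @param T1 Founding time in generations before present (>= 2).
#' @param founding Named numeric vector of founding ancestry proportions,
#'   summing to 1. The names define the model's ancestries.
#' @param pulses Tibble/data frame with columns `time`, `source`,
#'   `magnitude`, or `NULL` for no pulses. Sources must be founding
#'   ancestries or new ancestry names; times strictly between 1 and `T1`;
#'   magnitudes in \[0, 1\].
#' @param N Diploid population size used by the forward simulator.
#' @return An object of class `migration_model`.
#' @export
migration_model <- function(T1, founding, pulses = NULL, N = 5000) {
  if (T1 < 2) stop("founding time T1 must be >= 2 generations")
  if (is.null(names(founding)) || any(!nzchar(names(founding)))) {
    stop("founding proportions must be named by ancestry")
  }
  if (abs(sum(founding) - 1) > 1e-12) {
    stop("founding proportions must sum to 1")
  }
  if (any(founding < 0)) stop("founding proportions must be non-negative")
  if (is.null(pulses)) {
    pulses <- tibble::tibble(time = numeric(0), source = character(0),
                             magnitude = numeric(0))
  }
  pulses <- tibble::as_tibble(pulses)
  stopifnot(all(c("time", "source", "magnitude") %in% names(pulses)))
  if (nrow(pulses)) {
    if (any(pulses$time <= 1 | pulses$time >= T1)) {
      stop("pulse times must lie strictly between 1 and T1")
    }
    if (any(pulses$magnitude < 0 | pulses$magnitude > 1)) {
      stop("pulse magnitudes must lie in [0, 1]")
    }
  }
  ancestries <- union(names(founding), pulses$source)
  structure(
    list(T1 = T1, founding = founding,
         pulses = dplyr::arrange(pulses, dplyr::desc(.data$time)),
         ancestries = ancestries, N = N),
    class = "migration_model"
  )
}

#' @exportS3Method base::print
print.migration_model <- function(x, ...) {
  cat("<migration_model> founding at T1 =", format(x$T1), "gen:",
      paste(sprintf("%s=%.3f", names(x$founding), x$founding),
            collapse = ", "), "\n")
  if (nrow(x$pulses)) {
    for (i in seq_len(nrow(x$pulses))) {
      cat(sprintf("  pulse at t=%s: source %s, magnitude %.3f\n",
                  format(x$pulses$time[i]), x$pulses$source[i],
                  x$pulses$magnitude[i]))
    }
  }
  invisible(x)
}

# Internal event representation: integer-time replacement events, oldest
# first. Each event is a fraction `magnitude` of the population replaced by
# chromosomes drawn from a source *distribution* over ancestries. The
# founding event is a magnitude-1 replacement at ceiling(T1).
#
# Fractional times are smoothed so that likelihoods are continuous during
# optimization: a pulse at t = n + f (0 < f < 1) is split into a pulse at
# n + 1 of magnitude m*f and one at n of magnitude m*(1-f)/(1-m*f), which
# together replace exactly a fraction m. A fractional founding T1 = n + f
# becomes a full founding at n + 1 followed by a partial re-founding pulse
# of magnitude (1 - f) at n with the founding proportions, interpolating
# between founding at n (f -> 0) and at n + 1 (f -> 1).
discretize_migration_model <- function(model) {
  anc <- model$ancestries
  K <- length(anc)
  ev_time <- integer(0)
  ev_mag <- numeric(0)
  ev_src <- matrix(numeric(0), ncol = K, nrow = 0)
  add_event <- function(t, m, src) {
    if (m <= 0) return(invisible())
    ev_time <<- c(ev_time, as.integer(t))
    ev_mag <<- c(ev_mag, m)
    ev_src <<- rbind(ev_src, src)
  }
  fvec <- setNames(numeric(K), anc)
  fvec[names(model$founding)] <- model$founding

  T1 <- model$T1
  n1 <- floor(T1)
  f1 <- T1 - n1
  if (f1 < 1e-9) {
    add_event(n1, 1, fvec)
  } else {
    add_event(n1 + 1, 1, fvec)
    add_event(n1, 1 - f1, fvec)
  }
  if (nrow(model$pulses)) {
    for (i in seq_len(nrow(model$pulses))) {
      t <- model$pulses$time[i]
      m <- model$pulses$magnitude[i]
      src <- setNames(numeric(K), anc)
      src[model$pulses$source[i]] <- 1
      n <- floor(t)
      f <- t - n
      if (f < 1e-9) {
        add_event(n, m, src)
      } else {
        add_event(n + 1, m * f, src)
        if (m * f < 1) add_event(n, m * (1 - f) / (1 - m * f), src)
      }
    }
  }
  # combine events at the same generation, applying younger pulses after
  # older ones within the generation is not needed: coincident events are
  # merged as sequential replacements in listed (founding-first) order.
  ord <- order(ev_time, decreasing = TRUE)
  list(time = ev_time[ord], mag = pmin(ev_mag[ord], 1),
       src = ev_src[ord, , drop = FALSE], ancestries = anc)
}

#' Expected ancestry proportions through time
#'
#' Applies the pulse recursion `a(t) = (1 - m) a(t+1) + m e_s` from the
#' founding generation to the present, returning the expected ancestry
#' proportion vector at every generation. Proportions are constant between
#' pulses.
#'
#' @param model A [migration_model()].
#' @return A tibble with columns `generation` (from `ceiling(T1)` down
#'   to 1) and one column per ancestry. Row `generation == 1` holds the
#'   present-day proportions.
#' @export
ancestry_trajectory <- function(model) {
  d <- discretize_migration_model(model)
  K <- length(d$ancestries)
  Tmax <- max(d$time)
  a <- matrix(NA_real_, nrow = Tmax, ncol = K,
              dimnames = list(NULL, d$ancestries))
  cur <- rep(0, K)
  for (g in Tmax:1) {
    hits <- which(d$time == g)
    for (e in hits) cur <- (1 - d$mag[e]) * cur + d$mag[e] * d$src[e, ]
    a[g, ] <- cur
  }
  out <- tibble::as_tibble(a)
  out$generation <- seq_len(Tmax)
  dplyr::arrange(out[, c("generation", d$ancestries)],
                 dplyr::desc(.data$generation))
}

#' Present-day ancestry proportions of a model
#'
#' @param model A [migration_model()].
#' @return Named vector of present-day proportions.
#' @export
present_proportions <- function(model) {
  tr <- ancestry_trajectory(model)
  unlist(tr[tr$generation == 1, model$ancestries])
}
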