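# Ancestry-specific PCA (ASPCA) on masked haplotypes.
#
# Admixed haplotypes are masked to one continental ancestry (all other
# sites set to missing) and analysed jointly with fully observed
# sub-continental reference haplotypes by a regularized alternating
# least squares PCA that operates on the observed entries only.

#' Mask a panel to one continental ancestry
#'
#' Keeps alleles only at variants inside windows called `target` (the
#' thresholded posterior calls), setting everything else to missing.
#' Haplotypes whose genome-wide fraction of target-called variants falls
#' below `min_global_fraction` are excluded with a message.
#'
#' @param panel Admixed [haplotype_panel()].
#' @param painting An [infer_local_ancestry()] result for the panel (its
#'   `call` column drives the mask).
#' @param target Target ancestry label.
#' @param min_global_fraction Minimum genome-wide target fraction for a
#'   haplotype to be retained (e.g. 0.03 or 0.25).
#' @return Object of class `masked_haplotypes`: `X` (matrix with NA),
#'   `rows` (tibble: `hap_id`, `group`, `population`), `variants`,
#'   `target`.
#' @export
mask_by_ancestry <- function(panel, painting, target,
                             min_global_fraction = 0) {
  info <- painting$window_info
  calls <- painting$calls
  n_var <- nrow(panel$variants)
  keep_rows <- list()
  X <- panel$alleles
  Xm <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  pops <- hap_populations(panel)
  retained <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    hid <- panel$haplotypes$hap_id[i]
    cc <- calls[calls$hap_id == hid, ]
    cc <- cc[order(cc$window), ]
    winsel <- cc$window[cc$call == target]
    vidx <- unlist(lapply(winsel, function(w) {
      info$first_idx[w]:info$last_idx[w]
    }))
    frac <- length(vidx) / n_var
    if (frac < min_global_fraction || !length(vidx)) {
      message("haplotype ", hid, " excluded: target fraction ",
              format(frac, digits = 3), " < ", min_global_fraction)
      next
    }
    Xm[i, vidx] <- X[i, vidx]
    retained[i] <- TRUE
  }
  if (!any(retained)) stop("no haplotypes retained after masking")
  structure(
    list(X = Xm[retained, , drop = FALSE],
         rows = tibble::tibble(
           hap_id = panel$haplotypes$hap_id[retained],
           group = "admixed",
           population = pops[retained]
         ),
         variants = panel$variants, target = target),
    class = "masked_haplotypes"
  )
}

#' @exportS3Method base::print
print.masked_haplotypes <- function(x, ...) {
  cat("<masked_haplotypes> target ", x$target, ": ", nrow(x$X), " rows x ",
      ncol(x$X), " variants, ",
      format(100 * mean(is.na(x$X)), digits = 3), "% missing\n", sep = "")
  invisible(x)
}

#' Append fully observed reference rows to a masked matrix
#'
#' @param masked A [mask_by_ancestry()] result (or `masked_haplotypes`
#'   built directly).
#' @param refs Reference [haplotype_panel()] on the same variants.
#' @return A `masked_haplotypes` with the reference rows appended
#'   (`group = "reference"`).
#' @export
add_reference_rows <- function(masked, refs) {
  stopifnot(ncol(masked$X) == ncol(refs$alleles))
  X <- rbind(masked$X, refs$alleles)
  rows <- dplyr::bind_rows(
    masked$rows,
    tibble::tibble(hap_id = refs$haplotypes$hap_id, group = "reference",
                   population = hap_populations(refs))
  )
  structure(list(X = X, rows = rows, variants = masked$variants,
                 target = masked$target),
            class = "masked_haplotypes")
}

#' Build a masked matrix directly from a matrix with missing entries
#'
#' Mostly a testing convenience.
#'
#' @param X Matrix of 0/1 with NA for masked entries; rownames required.
#' @param group,population Row metadata vectors (recycled).
#' @param target Target ancestry label.
#' @return A `masked_haplotypes`.
#' @export
masked_haplotypes <- function(X, group = "admixed", population = "admixed",
                              target = "target") {
  stopifnot(!is.null(rownames(X)))
  structure(
    list(X = X,
         rows = tibble::tibble(hap_id = rownames(X),
                               group = rep_len(group, nrow(X)),
                               population = rep_len(population, nrow(X))),
         variants = NULL, target = target),
    class = "masked_haplotypes"
  )
}

#' Ancestry-specific PCA by regularized alternating least squares
#'
#' Minimizes `sum_observed (x_rc - mu_c - sum_k u_rk w_ck)^2 +
#' lambda (||U||^2 + ||W||^2)` where `mu_c` is the observed-entry column
#' mean, alternating exact row and column least-squares updates until the
#' relative objective change drops below `tol`. The final components are
#' orthonormalized (loadings orthonormal, scores ordered by variance) and
#' sign-fixed so each component's largest-magnitude loading is positive.
#' With no missing data and `lambda = 0` the scores equal classical PCA
#' scores up to component sign.
#'
#' @param masked A `masked_haplotypes` (typically [add_reference_rows()]
#'   output).
#' @param n_components Number of components (default 2).
#' @param lambda Ridge penalty; default `1e-3 * n_observed / n_rows`.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum ALS sweeps; non-convergence warns and returns
#'   the partial result.
#' @param min_observed Rows with fewer observed sites are dropped (with a
#'   message). Default 500, suited to genome-scale input; lower it for
#'   small matrices.
#' @param seed Seed for the random initialization.
#' @return Object of class `aspca_fit`: `scores`, `loadings`, `center`,
#'   `rows`, `lambda`, `iterations`, `objective`, `converged`, `sdev`.
#' @export
fit_aspca <- function(masked, n_components = 2, lambda = NULL, tol = 1e-6,
                      max_iter = 1000, min_observed = 500, seed = 1) {
  X <- masked$X
  rows <- masked$rows
  obs_per_row <- rowSums(!is.na(X))
  drop_r <- obs_per_row < min_observed
  if (any(drop_r)) {
    message(sum(drop_r), " row(s) dropped: fewer than ", min_observed,
            " observed sites")
    X <- X[!drop_r, , drop = FALSE]
    rows <- rows[!drop_r, ]
  }
  if (nrow(X) < 2) stop("fewer than 2 rows retained")
  obs_per_col <- colSums(!is.na(X))
  drop_c <- obs_per_col < 2
  if (any(drop_c)) {
    message(sum(drop_c), " column(s) dropped: observed in < 2 rows")
    X <- X[, !drop_c, drop = FALSE]
  }
  M <- !is.na(X)
  n <- nrow(X); L <- ncol(X); k <- n_components
  if (is.null(lambda)) lambda <- 1e-3 * sum(M) / n
  mu <- colSums(X * M, na.rm = TRUE) / colSums(M)
  Z <- sweep(X, 2, mu)
  Z[!M] <- 0
  Mn <- M * 1

  set.seed(seed)
  W <- matrix(rnorm(L * k, sd = 0.1), L, k)
  U <- matrix(0, n, k)
  obj <- Inf
  trace <- numeric(0)
  converged <- FALSE
  solve_side <- function(Wm, Mside, Zside, lam) {
    # exact LS update for all rows of one side simultaneously:
    # A_r = sum_c M_rc w_c w_c' + lam I ; b_r = sum_c M_rc z_rc w_c
    kk <- ncol(Wm)
    nr <- nrow(Mside)
    A <- array(0, c(nr, kk, kk))
    for (i in seq_len(kk)) {
      for (j in i:kk) {
        v <- drop(Mside %*% (Wm[, i] * Wm[, j]))
        A[, i, j] <- v
        A[, j, i] <- v
      }
    }
    B <- Zside %*% Wm
    out <- matrix(0, nr, kk)
    if (kk == 1) {
      out[, 1] <- B[, 1] / (A[, 1, 1] + lam)
    } else if (kk == 2) {
      a <- A[, 1, 1] + lam; b <- A[, 1, 2]; d <- A[, 2, 2] + lam
      det <- a * d - b^2
      out[, 1] <- (d * B[, 1] - b * B[, 2]) / det
      out[, 2] <- (a * B[, 2] - b * B[, 1]) / det
    } else {
      for (r in seq_len(nr)) {
        out[r, ] <- solve(A[r, , ] + diag(lam, kk), B[r, ])
      }
    }
    out
  }
  U_prev <- NULL
  for (it in seq_len(max_iter)) {
    U <- solve_side(W, Mn, Z, lambda)
    W <- solve_side(U, t(Mn), t(Z), lambda)
    R <- (Z - U %*% t(W)) * Mn
    new_obj <- sum(R^2) + lambda * (sum(U^2) + sum(W^2))
    trace <- c(trace, new_obj)
    # converge on both the objective and the fitted low-rank surface:
    # the objective flattens well before the subspace settles
    fit_now <- U %*% t(W)
    delta_fit <- if (is.null(U_prev)) Inf else {
      max(abs(fit_now - U_prev)) / max(max(abs(fit_now)), 1e-12)
    }
    U_prev <- fit_now
    if (is.finite(obj) &&
        abs(obj - new_obj) <= tol * max(abs(obj), 1e-12) &&
        delta_fit <= tol * 10) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged) {
    warning("ASPCA did not converge in ", max_iter,
            " iterations; returning partial result")
  }
  # orthonormalize: loadings orthonormal, scores carry the variance
  qu <- qr(U); qw <- qr(W)
  sv <- svd(qr.R(qu) %*% t(qr.R(qw)))
  scores <- qr.Q(qu) %*% sv$u %*% diag(sv$d, k)
  loadings <- qr.Q(qw) %*% sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rows$hap_id
  colnames(scores) <- paste0("ASPC", seq_len(k))
  structure(
    list(scores = scores, loadings = loadings, center = mu, rows = rows,
         lambda = lambda, iterations = length(trace), objective = trace,
         converged = converged,
         sdev = apply(scores, 2, sd)),
    class = "aspca_fit"
  )
}

#' @exportS3Method base::print
print.aspca_fit <- function(x, ...) {
  cat("<aspca_fit> ", nrow(x$scores), " rows, ", ncol(x$scores),
      " components, lambda = ", format(x$lambda, digits = 3),
      ", ", x$iterations, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.aspca_fit <- function(x, ...) {
  dplyr::bind_cols(x$rows, tibble::as_tibble(x$scores))
}

#' @export
glance.aspca_fit <- function(x, ...) {
  tibble::tibble(n_rows = nrow(x$scores), n_components = ncol(x$scores),
                 lambda = x$lambda, iterations = x$iterations,
                 converged = x$converged,
                 objective = tail(x$objective, 1))
}

#' Centroid-deviation bootstrap test
#'
#' Tests whether an admixed group's centroid deviates from a pooled
#' two-subgroup reference cluster more than the subgroups deviate from
#' each other. The observed statistic combines two-sample t-tests on the
#' first two score axes by Fisher's method,
#' `S = -2 (ln p1 + ln p2)`; the null distribution is built by
#' bootstrap-resampling the two reference subgroups and computing the same
#' statistic between them. One-tailed
#' `p = (1 + #\{S_null >= S_obs\}) / (n_boot + 1)`.
#'
#' @param scores Score matrix (first two columns used).
#' @param subgroupA,subgroupB,admixed_group Row indices (or rowname
#'   vectors) of the two reference subgroups and the admixed group; each
#'   needs >= 3 rows.
#' @param n_boot Number of bootstrap replicates (default 10000; must be
#'   >= 1).
#' @param seed Optional seed.
#' @return List with `p_value`, `statistic`, `null_statistics`.
#' @export
centroid_deviation_test <- function(scores, subgroupA, subgroupB,
                                    admixed_group, n_boot = 10000,
                                    seed = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- function(g) {
    if (is.character(g)) match(g, rownames(scores)) else g
  }
  A <- idx(subgroupA); B <- idx(subgroupB); G <- idx(admixed_group)
  if (min(length(A), length(B), length(G)) < 3) {
    stop("each group needs at least 3 rows")
  }
  fisher_stat <- function(g1, g2) {
    ps <- vapply(1:2, function(j) {
      x <- scores[g1, j]; y <- scores[g2, j]
      if (sd(x) < 1e-12 && sd(y) < 1e-12) {
        stop("degenerate variance in centroid test")
      }
      t.test(x, y)$p.value
    }, 1.0)
    -2 * sum(log(pmax(ps, 1e-300)))
  }
  S_obs <- fisher_stat(G, c(A, B))
  S_null <- vapply(seq_len(n_boot), function(b) {
    fisher_stat(sample(A, length(A), replace = TRUE),
                sample(B, length(B), replace = TRUE))
  }, 1.0)
  list(p_value = (1 + sum(S_null >= S_obs)) / (n_boot + 1),
       statistic = S_obs, null_statistics = S_null)
}

#' Wilcoxon rank test along one score axis
#'
#' Rank-sum (Mann-Whitney) comparison of one axis between two groups;
#' exact null when the combined size is at most 20 (and no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param scores_axis Numeric vector of scores along one axis.
#' @param groupA,groupB Index vectors into `scores_axis`.
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   two-sided).
#' @return Htest-like list with `p_value` and `statistic`.
#' @export
axis_rank_test <- function(scores_axis, groupA, groupB,
                           alternative = "two.sided") {
  x <- scores_axis[groupA]; y <- scores_axis[groupB]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y)) <= 20 &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact)
  )
  list(p_value = ht$p.value, statistic = unname(ht$statistic))
}

#' Classify tracts into length classes
#'
#' Two-class mode splits at 50 cM (`short` < 50, `long` >= 50; the
#' boundary value closes the upper class). The intermediate class used to
#' guard against short-tract mis-assignment is the open interval
#' (5, 50) cM, a subset of `short`, returned as the `is_medium` flag.
#'
#' @param tracts A [tract_set()] tibble.
#' @param cutoffs_cM `c(medium_lower, short_long_cut)`, default `c(5, 50)`.
#' @return The tract tibble with `size_class` and `is_medium` columns.
#' @export
split_tracts_by_length <- function(tracts, cutoffs_cM = c(5, 50)) {
  dplyr::mutate(
    tracts,
    size_class = ifelse(.data$length_cM < cutoffs_cM[2], "short", "long"),
    is_medium = .data$length_cM > cutoffs_cM[1] &
      .data$length_cM < cutoffs_cM[2]
  )
}

#' Restrict a masked matrix to sites inside one tract class
#'
#' For each admixed haplotype, keeps observed entries only at variants
#' inside its tracts of the requested class; haplotypes with no tract of
#' the class lose all observations and are omitted. Reference rows are
#' restricted to the union of sites retained in any admixed row.
#'
#' @param masked A `masked_haplotypes` (possibly with reference rows).
#' @param classed_tracts Output of [split_tracts_by_length()] for the
#'   masked target ancestry; `hap_id` must match admixed rows.
#' @param class `"short"`, `"long"`, or `"medium"`.
#' @return A restricted `masked_haplotypes`.
#' @export
sizeclass_sites <- function(masked, classed_tracts, class) {
  stopifnot(class %in% c("short", "long", "medium"))
  sel <- if (class == "medium") classed_tracts$is_medium else
    classed_tracts$size_class == class
  ct <- classed_tracts[sel, ]
  variants <- masked$variants
  X <- masked$X
  adm <- which(masked$rows$group == "admixed")
  keep_row <- rep(TRUE, nrow(X))
  for (i in adm) {
    hid <- masked$rows$hap_id[i]
    tr <- ct[ct$hap_id == hid, ]
    inside <- rep(FALSE, ncol(X))
    for (b in seq_len(nrow(tr))) {
      inside <- inside | (variants$chrom == tr$chrom[b] &
                            variants$pos_cM >= tr$start_cM[b] &
                            variants$pos_cM <= tr$end_cM[b])
    }
    X[i, !inside] <- NA
    if (!any(!is.na(X[i, ]))) keep_row[i] <- FALSE
  }
  site_union <- colSums(!is.na(X[adm[keep_row[adm]], , drop = FALSE])) > 0
  X <- X[keep_row, site_union, drop = FALSE]
  structure(
    list(X = X, rows = masked$rows[keep_row, ],
         variants = variants[site_union, ], target = masked$target),
    class = "masked_haplotypes"
  )
}

#' Fit per-population Gaussians to reference score clusters
#'
#' Maximum-likelihood mean and covariance per population with `eps I`
#' shrinkage (`eps = 1e-4 * mean(diag(cov))`, floored at 1e-8).
#' Populations with fewer than 3 rows are dropped with a warning.
#'
#' @param scores Score matrix (>= 2 columns; the first two are used).
#' @param populations Population label per row.
#' @return Named list of `list(mean, cov)` per retained population.
#' @export
fit_cluster_gaussians <- function(scores, populations) {
  scores <- scores[, 1:2, drop = FALSE]
  out <- list()
  for (p in sort(unique(populations))) {
    s <- scores[populations == p, , drop = FALSE]
    if (nrow(s) < 3) {
      warning("population ", p, " dropped: fewer than 3 reference rows")
      next
    }
    mu <- colMeans(s)
    S <- cov(s) * (nrow(s) - 1) / nrow(s)
    eps <- 1e-4 * mean(diag(S))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
    out[[p]] <- list(mean = mu, cov = S + diag(eps, 2))
  }
  if (!length(out)) stop("no population with >= 3 reference rows")
  out
}

#' Source-assignment probabilities and cohort summary
#'
#' For each admixed row, evaluates the fitted per-population bivariate
#' normal densities (in log space, so underflow is harmless) and
#' normalizes them into assignment probabilities; then reports the mean
#' probability per population across individuals with its standard error,
#' and the means rescaled to sum to one across populations.
#'
#' @param admixed_scores Score matrix of admixed rows (rownames = ids).
#' @param gaussians [fit_cluster_gaussians()] output.
#' @param class Optional tract-length class label carried into the output.
#' @return List of class `source_assignment`: `per_individual` (tibble:
#'   `hap_id`, `population`, `probability`, `class`) and `summary`
#'   (tibble: `population`, `mean_prob`, `sem`, `rescaled_mean`, `class`).
#' @export
assignment_summary <- function(admixed_scores, gaussians, class = NA) {
  if (!nrow(admixed_scores)) stop("no admixed rows to assign")
  s <- admixed_scores[, 1:2, drop = FALSE]
  pops <- names(gaussians)
  logd <- vapply(pops, function(p) {
    g <- gaussians[[p]]
    R <- chol(g$cov)
    apply(s, 1, function(x) log_mvn(x, g$mean, R))
  }, numeric(nrow(s)))
  logd <- matrix(logd, nrow = nrow(s),
                 dimnames = list(rownames(s), pops))
  pr <- exp(logd - apply(logd, 1, max))
  pr <- pr / rowSums(pr)
  per_ind <- tibble::as_tibble(pr) |>
    dplyr::mutate(hap_id = rownames(s)) |>
    tidyr::pivot_longer(dplyr::all_of(pops), names_to = "population",
                        values_to = "probability") |>
    dplyr::mutate(class = class)
  mean_p <- colMeans(pr)
  sem <- apply(pr, 2, sd) / sqrt(nrow(pr))
  structure(
    list(per_individual = per_ind,
         summary = tibble::tibble(
           population = pops, mean_prob = mean_p, sem = sem,
           rescaled_mean = mean_p / sum(mean_p), class = class
         )),
    class = "source_assignment"
  )
}

#' @exportS3Method base::print
print.source_assignment <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

# least-squares projection of partially observed rows onto fixed loadings
project_masked_rows <- function(X, center, loadings) {
  k <- ncol(loadings)
  out <- matrix(NA_real_, nrow(X), k,
                dimnames = list(rownames(X), paste0("PC", seq_len(k))))
  for (i in seq_len(nrow(X))) {
    o <- which(!is.na(X[i, ]))
    Wo <- loadings[o, , drop = FALSE]
    z <- X[i, o] - center[o]
    out[i, ] <- qr.solve(crossprod(Wo) + diag(1e-10, k), crossprod(Wo, z))
  }
  out
}

#' Size-stratified source assignment
#'
#' Implements the per-individual size-based ASPCA: for each tract-length
#' class and each admixed haplotype, restricts the analysis to the
#' haplotype's observed sites in that class, runs a classical PCA of the
#' reference populations on those sites, fits per-population Gaussians to
#' the reference scores, projects the haplotype, and records its
#' assignment probabilities. Results are aggregated per class by
#' [assignment_summary()]'s rules.
#'
#' @param masked A `masked_haplotypes` including reference rows
#'   ([add_reference_rows()]).
#' @param classed_tracts [split_tracts_by_length()] output for the target
#'   ancestry.
#' @param classes Classes to analyse (default `c("short", "long")`).
#' @param n_pcs Number of PCs (2).
#' @param min_sites Minimum observed sites for a haplotype-class
#'   combination.
#' @return Tibble: one row per class x population with `mean_prob`,
#'   `sem`, `rescaled_mean`, `n_haplotypes`.
#' @export
size_stratified_assignment <- function(masked, classed_tracts,
                                       classes = c("short", "long"),
                                       n_pcs = 2, min_sites = 50) {
  ref_rows <- which(masked$rows$group == "reference")
  if (!length(ref_rows)) stop("masked matrix has no reference rows")
  out <- list()
  for (cl in classes) {
    sub <- sizeclass_sites(masked, classed_tracts, cl)
    adm <- which(sub$rows$group == "admixed")
    refs_all <- which(sub$rows$group == "reference")
    probs <- list()
    for (i in adm) {
      o <- which(!is.na(sub$X[i, ]))
      if (length(o) < min_sites) next
      Xr <- sub$X[refs_all, o, drop = FALSE]
      pc <- tryCatch(stats::prcomp(Xr, center = TRUE, scale. = FALSE),
                     error = function(e) NULL)
      if (is.null(pc) || ncol(pc$x) < n_pcs) next
      ref_scores <- pc$x[, 1:n_pcs, drop = FALSE]
      ga <- fit_cluster_gaussians(ref_scores,
                                  sub$rows$population[refs_all])
      hs <- matrix(sub$X[i, o], 1,
                   dimnames = list(sub$rows$hap_id[i], NULL))
      sc <- project_masked_rows(hs, pc$center,
                                pc$rotation[, 1:n_pcs, drop = FALSE])
      probs[[length(probs) + 1]] <-
        assignment_summary(sc, ga, class = cl)$per_individual
    }
    if (!length(probs)) next
    pi_tb <- dplyr::bind_rows(probs)
    smry <- pi_tb |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(mean_prob = mean(.data$probability),
                       sem = sd(.data$probability) /
                         sqrt(dplyr::n()),
                       n_haplotypes = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(rescaled_mean = .data$mean_prob / sum(.data$mean_prob),
                    class = cl)
    out[[cl]] <- smry
  }
  dplyr::bind_rows(out)
}
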