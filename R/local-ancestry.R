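# PCA-window HMM local ancestry inference.
#
# Reference haplotypes are pooled and, in windows of `window_size` SNPs,
# projected onto the first `n_pcs` principal components; per-population
# window scores are modelled as multivariate normals. An admixed haplotype
# is scored window by window and decoded with an HMM whose transition
# matrix between adjacent windows at genetic distance d Morgans is
#   P(i -> j) = exp(-g d) I[i == j] + (1 - exp(-g d)) q_j,
# with g an effective generations-since-admixture parameter and q the
# ancestry proportions.

#' Fit a window PCA model from reference panels
#'
#' Splits each chromosome into consecutive windows of `window_size`
#' variants (a short remainder is merged into the final full window),
#' computes a PCA of the pooled, centred reference alleles per window, and
#' fits a per-population mean and covariance of the window scores with
#' covariance shrinkage `Sigma + eps I`, `eps = 1e-4 * mean(diag(Sigma))`.
#' Windows monomorphic across all references are flagged uninformative and
#' contribute equal likelihoods.
#'
#' @param refs A [haplotype_panel()] with at least two population labels
#'   and at least three haplotypes per population.
#' @param window_size Variants per window (default 70).
#' @param n_pcs Number of principal components retained (default 2).
#' @return Object of class `window_model`.
#' @export
fit_window_model <- function(refs, window_size = 70, n_pcs = 2) {
  pops <- hap_populations(refs)
  upops <- sort(unique(pops))
  if (length(upops) < 2) stop("need at least two reference populations")
  tab <- table(pops)
  if (any(tab < 3)) {
    stop("each reference population needs >= 3 haplotypes")
  }
  variants <- refs$variants
  windows <- list()
  for (chr in unique(variants$chrom)) {
    vidx <- which(variants$chrom == chr)
    n <- length(vidx)
    if (window_size > n) {
      stop("window_size exceeds variant count on chromosome ", chr)
    }
    n_win <- max(1L, n %/% window_size)
    starts <- (seq_len(n_win) - 1L) * window_size + 1L
    ends <- starts + window_size - 1L
    ends[n_win] <- n # remainder merged into final window
    for (w in seq_len(n_win)) {
      idx <- vidx[starts[w]:ends[w]]
      windows[[length(windows) + 1]] <- list(chrom = chr, idx = idx)
    }
  }

  fit_one <- function(win) {
    X <- refs$alleles[, win$idx, drop = FALSE]
    center <- colMeans(X)
    Xc <- sweep(X, 2, center)
    informative <- any(abs(Xc) > 1e-12)
    if (!informative) {
      return(c(win, list(center = center,
                         loadings = matrix(0, length(center), n_pcs),
                         stats = NULL, informative = FALSE)))
    }
    sv <- svd(Xc, nu = 0, nv = n_pcs)
    loadings <- sv$v
    if (ncol(loadings) < n_pcs) {
      loadings <- cbind(loadings,
                        matrix(0, nrow(loadings), n_pcs - ncol(loadings)))
    }
    scores <- Xc %*% loadings
    stats <- lapply(upops, function(p) {
      s <- scores[pops == p, , drop = FALSE]
      mu <- colMeans(s)
      S <- cov(s) * (nrow(s) - 1) / nrow(s) # ML covariance
      eps <- 1e-4 * mean(diag(S))
      if (!is.finite(eps) || eps <= 0) eps <- 1e-8
      S <- S + diag(eps, n_pcs)
      list(mean = mu, cov = S, chol = chol(S))
    })
    names(stats) <- upops
    c(win, list(center = center, loadings = loadings, stats = stats,
                informative = TRUE))
  }
  fitted <- lapply(windows, fit_one)
  mid_cM <- vapply(fitted, function(w) {
    cm <- variants$pos_cM[w$idx]
    cm[ceiling(length(cm) / 2)]
  }, 1.0)
  structure(
    list(windows = fitted, populations = upops, n_pcs = n_pcs,
         window_size = window_size, variants = variants,
         window_info = tibble::tibble(
           window = seq_along(fitted),
           chrom = vapply(fitted, function(w) w$chrom, ""),
           first_idx = vapply(fitted, function(w) w$idx[1], 1L),
           last_idx = vapply(fitted, function(w) w$idx[length(w$idx)], 1L),
           mid_cM = mid_cM,
           informative = vapply(fitted, function(w) w$informative, TRUE)
         )),
    class = "window_model"
  )
}

#' @exportS3Method base::print
print.window_model <- function(x, ...) {
  cat("<window_model> ", length(x$windows), " windows x ",
      length(x$populations), " populations (",
      paste(x$populations, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

log_mvn <- function(s, mu, R) {
  # R = chol(cov); bivariate (or n_pcs-variate) normal log density
  z <- backsolve(R, s - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(R))) - 0.5 * length(s) * log(2 * pi)
}

#' Window log-likelihoods of a haplotype under each reference population
#'
#' @param hap Numeric 0/1 vector matching the model's variants.
#' @param model A [fit_window_model()] result.
#' @return Windows x populations matrix of log bivariate-normal densities;
#'   uninformative windows get equal (zero) log densities.
#' @export
window_loglikelihoods <- function(hap, model) {
  if (length(hap) != nrow(model$variants)) {
    stop("haplotype length does not match model variants")
  }
  K <- length(model$populations)
  out <- matrix(0, nrow = length(model$windows), ncol = K,
                dimnames = list(NULL, model$populations))
  for (w in seq_along(model$windows)) {
    win <- model$windows[[w]]
    if (!win$informative) next
    s <- drop(crossprod(win$loadings, hap[win$idx] - win$center))
    out[w, ] <- vapply(model$populations, function(p) {
      st <- win$stats[[p]]
      log_mvn(s, st$mean, st$chol)
    }, 1.0)
  }
  out
}

#' HMM transition matrix between adjacent windows
#'
#' `P(i -> j) = exp(-g d) I(i = j) + (1 - exp(-g d)) q_j`. `q` is the
#' stationary distribution of this kernel for any `g`, `d`.
#'
#' @param g Generations parameter (> 0).
#' @param d_morgans Genetic distance between windows in Morgans (>= 0).
#' @param q Ancestry proportion vector on the simplex.
#' @return K x K stochastic matrix.
#' @export
transition_matrix <- function(g, d_morgans, q) {
  stopifnot(g > 0, d_morgans >= 0, abs(sum(q) - 1) < 1e-9)
  e <- exp(-g * d_morgans)
  e * diag(length(q)) + (1 - e) * matrix(q, nrow = length(q),
                                         ncol = length(q), byrow = TRUE)
}

# distances in Morgans between consecutive window midpoints
window_distances <- function(model) {
  info <- model$window_info
  d <- diff(info$mid_cM) / 100
  # chromosome changes: effectively unlinked
  d[info$chrom[-1] != info$chrom[-nrow(info)]] <- 1e6
  pmax(d, 0)
}

forward_pass <- function(loglik, g, q, distances) {
  W <- nrow(loglik)
  K <- ncol(loglik)
  if (any(apply(loglik, 1, function(r) all(!is.finite(r))))) {
    stop("window with all -Inf log-likelihoods")
  }
  mx <- apply(loglik, 1, max)
  e <- exp(loglik - mx)
  alpha <- matrix(0, W, K)
  cvec <- numeric(W)
  a <- q * e[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (W > 1) {
    for (w in 2:W) {
      P <- transition_matrix(g, distances[w - 1], q)
      a <- drop(alpha[w - 1, ] %*% P) * e[w, ]
      cvec[w] <- sum(a)
      alpha[w, ] <- a / cvec[w]
    }
  }
  list(alpha = alpha, e = e, loglik = sum(log(cvec)) + sum(mx))
}

#' Forward-backward posterior decoding
#'
#' @param loglik Windows x K matrix from [window_loglikelihoods()].
#' @param g Generations parameter.
#' @param q Ancestry proportions (initial and transition target
#'   distribution).
#' @param distances Morgans between consecutive windows (length
#'   `nrow(loglik) - 1`).
#' @return Windows x K matrix of posterior probabilities (rows sum to 1);
#'   attribute `"loglik"` holds the total forward log-likelihood.
#' @export
posterior_decode <- function(loglik, g, q, distances) {
  W <- nrow(loglik)
  K <- ncol(loglik)
  fw <- forward_pass(loglik, g, q, distances)
  beta <- matrix(0, W, K)
  beta[W, ] <- 1
  if (W > 1) {
    for (w in (W - 1):1) {
      P <- transition_matrix(g, distances[w], q)
      b <- drop(P %*% (fw$e[w + 1, ] * beta[w + 1, ]))
      beta[w, ] <- b / sum(b)
    }
  }
  post <- fw$alpha * beta
  post <- post / rowSums(post)
  colnames(post) <- colnames(loglik)
  attr(post, "loglik") <- fw$loglik
  post
}

#' Total forward log-likelihood of a haplotype
#'
#' @inheritParams posterior_decode
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(loglik, g, q, distances) {
  forward_pass(loglik, g, q, distances)$loglik
}

#' Viterbi decoding with thresholded posterior calls
#'
#' Computes the maximum a posteriori state path (ties broken toward the
#' lowest ancestry index) and, separately, per-window calls thresholded at
#' `threshold` on the forward-backward posterior, with `"unknown"` where
#' the maximum posterior falls below the threshold.
#'
#' @inheritParams posterior_decode
#' @param threshold Posterior call threshold (default 0.9).
#' @return Tibble with columns `window`, `viterbi`, `call`,
#'   `max_posterior`, plus the posterior matrix as attribute
#'   `"posterior"`.
#' @export
viterbi_decode <- function(loglik, g, q, distances, threshold = 0.9) {
  W <- nrow(loglik)
  K <- ncol(loglik)
  labs <- colnames(loglik)
  if (is.null(labs)) labs <- as.character(seq_len(K))
  if (any(apply(loglik, 1, function(r) all(!is.finite(r))))) {
    stop("window with all -Inf log-likelihoods")
  }
  delta <- log(q) + loglik[1, ]
  psi <- matrix(0L, W, K)
  if (W > 1) {
    for (w in 2:W) {
      logP <- log(transition_matrix(g, distances[w - 1], q))
      cand <- delta + logP # K x K: cand[i, j] path ending i then j
      psi[w, ] <- apply(cand, 2, which.max) # first max = lowest index
      delta <- apply(cand, 2, max) + loglik[w, ]
    }
  }
  path <- integer(W)
  path[W] <- which.max(delta)
  if (W > 1) for (w in (W - 1):1) path[w] <- psi[w + 1, path[w + 1]]
  post <- posterior_decode(loglik, g, q, distances)
  mp <- apply(post, 1, max)
  call_idx <- apply(post, 1, which.max)
  out <- tibble::tibble(
    window = seq_len(W),
    viterbi = labs[path],
    call = ifelse(mp >= threshold, labs[call_idx], "unknown"),
    max_posterior = mp
  )
  attr(out, "posterior") <- post
  out
}

#' Optimize the HMM generations parameter for a population
#'
#' Golden-section search on log g maximizing the summed forward
#' log-likelihood over the population's haplotypes, warning if the
#' optimum sits at a search bound.
#'
#' @param logliks List of windows x K log-likelihood matrices (one per
#'   haplotype).
#' @param q Ancestry proportions.
#' @param distances Inter-window distances in Morgans.
#' @param bounds Search interval for g (default `c(1, 500)`).
#' @param tol Relative tolerance on log g.
#' @return The optimized g (scalar), with attribute `"loglik"`.
#' @export
optimize_generations <- function(logliks, q, distances, bounds = c(1, 500),
                                 tol = 1e-4) {
  if (!length(logliks)) stop("no haplotypes supplied")
  obj <- function(lg) {
    g <- exp(lg)
    sum(vapply(logliks, forward_loglik, 1.0, g = g, q = q,
               distances = distances))
  }
  lo <- log(bounds[1]); hi <- log(bounds[2])
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- obj(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- obj(x1)
    }
  }
  g <- exp((lo + hi) / 2)
  if (g <= bounds[1] * 1.01 || g >= bounds[2] * 0.99) {
    warning("generations parameter at search bound (g = ",
            format(g, digits = 4), ")")
  }
  structure(g, loglik = max(f1, f2))
}

#' Merge per-window ancestry labels into tracts
#'
#' Consecutive windows with equal labels are merged; tract boundaries fall
#' at the midpoint between the last variant of one window and the first
#' variant of the next (in both cM and bp). A tract spanning all windows
#' of a chromosome is flagged whole-chromosome.
#'
#' @param labels Character vector of per-window ancestry labels (e.g. the
#'   `viterbi` column of [viterbi_decode()]).
#' @param model The [fit_window_model()] the windows came from.
#' @param hap_id Haplotype id recorded in the output.
#' @return A [tract_set()] tibble.
#' @export
calls_to_tracts <- function(labels, model, hap_id = "hap") {
  info <- model$window_info
  stopifnot(length(labels) == nrow(info))
  variants <- model$variants
  out <- list()
  for (chr in unique(info$chrom)) {
    wi <- info[info$chrom == chr, ]
    labs <- labels[wi$window]
    nw <- nrow(wi)
    # window edge coordinates
    first_cm <- variants$pos_cM[wi$first_idx]
    last_cm <- variants$pos_cM[wi$last_idx]
    first_bp <- variants$pos_bp[wi$first_idx]
    last_bp <- variants$pos_bp[wi$last_idx]
    cuts_cm <- (last_cm[-nw] + first_cm[-1]) / 2
    cuts_bp <- (last_bp[-nw] + first_bp[-1]) / 2
    edges_cm <- c(first_cm[1], cuts_cm, last_cm[nw])
    edges_bp <- c(first_bp[1], cuts_bp, last_bp[nw])
    r <- rle(labs)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1
    out[[length(out) + 1]] <- tibble::tibble(
      hap_id = hap_id, chrom = chr,
      start_cM = edges_cm[lo], end_cM = edges_cm[hi + 1],
      start_bp = edges_bp[lo], end_bp = edges_bp[hi + 1],
      ancestry = r$values,
      is_whole_chromosome = length(r$values) == 1
    )
  }
  res <- dplyr::bind_rows(out)
  res$end_bp <- pmax(res$end_bp, res$start_bp + 1e-9)
  res$end_cM <- pmax(res$end_cM, res$start_cM + 1e-9)
  dplyr::mutate(res, length_cM = .data$end_cM - .data$start_cM)
}

#' Decode local ancestry for every haplotype of a panel
#'
#' Convenience pipeline: window log-likelihoods, per-population `g`
#' optimization (one `g` for the whole cohort), forward-backward posterior
#' calls at `threshold` and Viterbi paths, plus merged Viterbi tracts.
#'
#' @param panel Admixed [haplotype_panel()].
#' @param model A [fit_window_model()] on reference panels sharing the
#'   panel's variants.
#' @param q Ancestry proportions; default uniform over the model's
#'   populations.
#' @param g Generations parameter; `NULL` (default) optimizes it by
#'   [optimize_generations()] over the cohort.
#' @param threshold Posterior call threshold.
#' @return List of class `ancestry_painting` with `calls` (tibble:
#'   `hap_id`, `window`, `viterbi`, `call`, `max_posterior`, posterior
#'   columns per ancestry), `tracts` (Viterbi [tract_set()]), `g`, and the
#'   model's `window_info`.
#' @export
infer_local_ancestry <- function(panel, model, q = NULL, g = NULL,
                                 threshold = 0.9) {
  K <- length(model$populations)
  if (is.null(q)) q <- rep(1 / K, K)
  distances <- window_distances(model)
  hap_ids <- panel$haplotypes$hap_id
  logliks <- lapply(seq_along(hap_ids), function(i) {
    window_loglikelihoods(panel$alleles[i, ], model)
  })
  if (is.null(g)) {
    g <- suppressWarnings(
      as.numeric(optimize_generations(logliks, q, distances))
    )
  }
  calls <- purrr::map2_dfr(logliks, hap_ids, function(ll, hid) {
    vt <- viterbi_decode(ll, g, q, distances, threshold = threshold)
    post <- attr(vt, "posterior")
    colnames(post) <- paste0("post_", colnames(post))
    dplyr::bind_cols(tibble::tibble(hap_id = hid), vt,
                     tibble::as_tibble(post))
  })
  tracts <- purrr::map2_dfr(split(calls, calls$hap_id)[unique(hap_ids)],
                            unique(hap_ids), function(cc, hid) {
    calls_to_tracts(cc$viterbi[order(cc$window)], model, hap_id = hid)
  })
  structure(list(calls = calls, tracts = tracts, g = g,
                 window_info = model$window_info,
                 populations = model$populations, threshold = threshold),
            class = "ancestry_painting")
}

#' @exportS3Method base::print
print.ancestry_painting <- function(x, ...) {
  cat("<ancestry_painting> ", length(unique(x$calls$hap_id)),
      " haplotypes, g = ", format(x$g, digits = 4), ", ",
      nrow(x$tracts), " tracts\n", sep = "")
  invisible(x)
}

#' Disjoint-HMM sub-continental deconvolution within ancestry blocks
#'
#' For each continental-ancestry block of a haplotype, fits a separate
#' window model on the sub-continental reference panel restricted to the
#' block's variant span and runs an independent HMM on that block alone,
#' so no information flows across block boundaries. Blocks shorter than
#' one window are skipped with a warning.
#'
#' @param hap Numeric 0/1 allele vector on the reference variant grid.
#' @param blocks [tract_set()] rows delimiting the haplotype's blocks of
#'   the target continental ancestry.
#' @param subrefs Sub-continental reference [haplotype_panel()] (>= 2
#'   populations) on the same variants as `hap`.
#' @param window_size,n_pcs Window model settings (defaults 70 and 2).
#' @param g Generations parameter of the within-block HMM.
#' @param q Sub-ancestry proportions; default uniform.
#' @return Tibble with one row per block window: `block`, `window`,
#'   `block_length_cM`, `n_windows`, one posterior column per
#'   sub-population.
#' @export
deconvolve_within_tracts <- function(hap, blocks, subrefs, window_size = 70,
                                     n_pcs = 2, g = 10, q = NULL) {
  upops <- sort(unique(hap_populations(subrefs)))
  if (length(upops) < 2) stop("need >= 2 sub-continental populations")
  if (is.null(q)) q <- rep(1 / length(upops), length(upops))
  variants <- subrefs$variants
  out <- list()
  for (b in seq_len(nrow(blocks))) {
    idx <- which(variants$chrom == blocks$chrom[b] &
                   variants$pos_cM >= blocks$start_cM[b] &
                   variants$pos_cM <= blocks$end_cM[b])
    if (length(idx) < window_size) {
      warning("block ", b, " shorter than one window; skipped")
      next
    }
    sub <- subset_panel_variants(subrefs, idx)
    wm <- fit_window_model(sub, window_size = window_size, n_pcs = n_pcs)
    ll <- window_loglikelihoods(hap[idx], wm)
    post <- posterior_decode(ll, g, q, window_distances(wm))
    attr(post, "loglik") <- NULL
    tb <- tibble::as_tibble(post)
    tb$block <- b
    tb$window <- seq_len(nrow(post))
    tb$block_length_cM <- blocks$end_cM[b] - blocks$start_cM[b]
    tb$n_windows <- nrow(post)
    out[[length(out) + 1]] <- tb
  }
  if (!length(out)) {
    return(tibble::tibble(block = integer(0), window = integer(0),
                          block_length_cM = numeric(0),
                          n_windows = integer(0)))
  }
  dplyr::bind_rows(out)[, c("block", "window", "block_length_cM",
                            "n_windows", upops)]
}

# restrict a panel to a variant index set
subset_panel_variants <- function(panel, idx) {
  structure(
    list(alleles = panel$alleles[, idx, drop = FALSE],
         haplotypes = panel$haplotypes,
         variants = panel$variants[idx, ],
         labels = panel$labels),
    class = "haplotype_panel"
  )
}

#' Confident sub-ancestry fraction by block size
#'
#' Counts only windows whose maximum posterior reaches `confidence`, and
#' reports, per block-size bin, the fraction of confident windows assigned
#' to sub-ancestry `target` among confident windows assigned to either
#' listed sub-ancestry. Empty bins are reported as `NA`.
#'
#' @param block_posteriors Output of [deconvolve_within_tracts()] (possibly
#'   row-bound over haplotypes).
#' @param target Sub-ancestry of interest (e.g. the older source).
#' @param other The contrasted sub-ancestry.
#' @param breaks Block-size bin edges in cM (covering observed sizes).
#' @param confidence Posterior confidence threshold (default 0.9).
#' @return Tibble with `bin`, `lower`, `upper`, `n_windows`, `fraction`.
#' @export
subancestry_fraction_by_block_size <- function(block_posteriors, target,
                                               other, breaks,
                                               confidence = 0.9) {
  bp <- block_posteriors
  stopifnot(all(c(target, other) %in% names(bp)))
  win_lab <- ifelse(bp[[target]] >= confidence, target,
                    ifelse(bp[[other]] >= confidence, other, NA))
  keep <- !is.na(win_lab)
  bin <- cut(bp$block_length_cM, breaks = breaks, include.lowest = TRUE)
  levs <- levels(bin)
  n_t <- tapply(win_lab[keep] == target, bin[keep], sum)[levs]
  n_o <- tapply(win_lab[keep] == other, bin[keep], sum)[levs]
  n_t[is.na(n_t)] <- 0; n_o[is.na(n_o)] <- 0
  tot <- n_t + n_o
  tibble::tibble(
    bin = levs,
    lower = head(breaks, -1), upper = breaks[-1],
    n_windows = as.integer(unname(tot)),
    fraction = unname(ifelse(tot > 0, n_t / tot, NA_real_))
  )
}
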