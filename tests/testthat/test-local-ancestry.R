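# PCA-window HMM: window models, transitions, decoding, g optimization,
# tract merging, and within-block deconvolution.

test_that("window PCA separates divergent panels and merges remainders", {
  set.seed(1)
  # two reference pops with disjoint fixed alleles in one window
  n_var <- 80
  variants <- variant_table("1", seq_len(n_var) * 1000,
                            seq_len(n_var) * 0.1)
  XA <- matrix(0L, 10, n_var)
  XB <- matrix(1L, 10, n_var)
  noise <- matrix(rbinom(20 * n_var, 1, 0.02), 20, n_var)
  X <- rbind(XA, XB)
  X <- abs(X - noise)
  rownames(X) <- c(paste0(rep(paste0("s", 1:5), each = 2), "_", 0:1),
                   paste0(rep(paste0("t", 1:5), each = 2), "_", 0:1))
  labels <- tibble::tibble(sample_id = c(paste0("s", 1:5), paste0("t", 1:5)),
                           population = rep(c("A", "B"), each = 5))
  panel <- haplotype_panel(X, variants, labels)
  wm <- fit_window_model(panel, window_size = 70)
  # 80 variants, window 70 -> single window holding the remainder
  expect_length(wm$windows, 1L)
  expect_equal(wm$window_info$last_idx, 80L)
  st <- wm$windows[[1]]$stats
  sep <- abs(st$A$mean[1] - st$B$mean[1])
  expect_gt(sep, 5 * sqrt(max(st$A$cov[1, 1], st$B$cov[1, 1])))
})

test_that("identical reference populations give matching window stats", {
  set.seed(2)
  f <- runif(140, 0.3, 0.7)
  pan <- simulate_reference_haplotypes(f, 40, seed = 3)
  labels <- pan$labels
  labels$population <- rep(c("A", "B"), each = 10)
  panel <- haplotype_panel(pan$alleles, pan$variants, labels)
  wm <- fit_window_model(panel, window_size = 70)
  for (w in wm$windows) {
    d <- sqrt(sum((w$stats$A$mean - w$stats$B$mean)^2))
    spread <- sqrt(mean(diag(w$stats$A$cov)))
    expect_lt(d, 2.5 * spread)   # means within sampling error
  }
})

test_that("window log-likelihoods follow the bivariate normal density", {
  # hand-built one-window model: score (0,0), mean (0,0), identity cov
  win <- list(chrom = "1", idx = 1:2, center = c(0.5, 0.5),
              loadings = diag(2),
              stats = list(P = list(mean = c(0, 0), cov = diag(2),
                                    chol = chol(diag(2)))),
              informative = TRUE)
  model <- structure(
    list(windows = list(win), populations = "P", n_pcs = 2,
         window_size = 2,
         variants = variant_table("1", c(1000, 2000), c(0.1, 0.2)),
         window_info = tibble::tibble(window = 1L, chrom = "1",
                                      first_idx = 1L, last_idx = 2L,
                                      mid_cM = 0.1, informative = TRUE)),
    class = "window_model"
  )
  ll <- window_loglikelihoods(c(0.5, 0.5), model)  # score exactly (0, 0)
  expect_equal(unname(ll[1, 1]), -log(2 * pi), tolerance = 1e-12)
})

test_that("a reference-like haplotype scores highest under its own panel", {
  setup <- make_two_pop_setup(seed = 5, n_variants = 350)
  wm <- fit_window_model(setup$refs, window_size = 70)
  newA <- simulate_reference_haplotypes(setup$freqs$A, 2, setup$variants,
                                        population = "A", seed = 99)
  ll <- window_loglikelihoods(newA$alleles[1, ], wm)
  expect_true(all(ll[, "A"] > ll[, "B"]))
})

test_that("uninformative (monomorphic) windows get equal log-likelihoods", {
  n_var <- 140
  variants <- variant_table("1", seq_len(n_var) * 1000,
                            seq_len(n_var) * 0.1)
  X <- cbind(matrix(0L, 12, 70),
             matrix(rbinom(12 * 70, 1, 0.5), 12, 70))
  rownames(X) <- paste0(rep(paste0("s", 1:6), each = 2), "_", 0:1)
  labels <- tibble::tibble(sample_id = paste0("s", 1:6),
                           population = rep(c("A", "B"), each = 3))
  panel <- haplotype_panel(X, variants, labels)
  wm <- fit_window_model(panel, window_size = 70)
  expect_false(wm$window_info$informative[1])
  ll <- window_loglikelihoods(rep(0, n_var), wm)
  expect_equal(unname(ll[1, "A"]), unname(ll[1, "B"]))
})

test_that("transition matrix matches its closed form and fixes q", {
  q <- c(0.2, 0.8)
  expect_equal(transition_matrix(10, 0, q), diag(2))
  P <- transition_matrix(10, 0.05, q)
  e <- exp(-0.5)
  expect_equal(P[1, 1], e + (1 - e) * 0.2, tolerance = 1e-12)
  expect_equal(P[1, 2], (1 - e) * 0.8, tolerance = 1e-12)
  expect_equal(P[1, 1], 0.6852, tolerance = 1e-4)
  expect_equal(P[1, 2], 0.3148, tolerance = 1e-4)
  # q is stationary for any g, d
  for (g in c(1, 17, 300)) {
    for (d in c(0.001, 0.3, 5)) {
      P <- transition_matrix(g, d, c(0.1, 0.3, 0.6))
      expect_equal(drop(c(0.1, 0.3, 0.6) %*% P), c(0.1, 0.3, 0.6),
                   tolerance = 1e-12)
      expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
    }
  }
})

test_that("forward-backward posteriors match exhaustive path enumeration", {
  set.seed(8)
  for (rep in 1:5) {
    W <- sample(2:6, 1); K <- sample(2:3, 1)
    loglik <- matrix(rnorm(W * K, sd = 2), W, K)
    q <- runif(K); q <- q / sum(q)
    d <- runif(W - 1, 0.01, 0.5)
    g <- runif(1, 2, 30)
    post <- posterior_decode(loglik, g, q, d)
    ref <- enumerate_hmm(loglik, g, q, d)
    expect_lt(max(abs(post - ref$posterior)), 1e-10)
    expect_equal(attr(post, "loglik"), ref$loglik, tolerance = 1e-10)
    expect_equal(rowSums(post), rep(1, W), tolerance = 1e-9)
  }
})

test_that("posterior decoding has the right degenerate limits", {
  q <- c(0.3, 0.7)
  ll <- matrix(c(1, -1), 1, 2)
  post <- posterior_decode(ll, 10, q, numeric(0))
  expect_equal(drop(post), q * exp(ll[1, ]) / sum(q * exp(ll[1, ])),
               tolerance = 1e-12, ignore_attr = TRUE) # single-window form
  # d -> Inf: windows decouple to the single-window form
  ll3 <- matrix(rnorm(6), 3, 2)
  post3 <- posterior_decode(ll3, 10, q, c(1e9, 1e9))
  for (w in 1:3) {
    expect_equal(post3[w, ], q * exp(ll3[w, ]) / sum(q * exp(ll3[w, ])),
                 tolerance = 1e-9)
  }
  expect_error(posterior_decode(matrix(-Inf, 1, 2), 10, q, numeric(0)),
               "-Inf")
})

test_that("Viterbi equals exhaustive argmax, breaks ties low, shifts out", {
  set.seed(9)
  for (rep in 1:5) {
    W <- 5; K <- 2
    loglik <- matrix(rnorm(W * K, sd = 2), W, K,
                     dimnames = list(NULL, c("1", "2")))
    q <- c(0.4, 0.6)
    d <- runif(W - 1, 0.01, 0.5)
    vt <- viterbi_decode(loglik, 12, q, d)
    ref <- enumerate_hmm(loglik, 12, q, d)
    expect_equal(match(vt$viterbi, colnames(loglik)),
                 unname(ref$viterbi))
    # adding a constant per window leaves the path unchanged
    vt2 <- viterbi_decode(loglik + 3.7, 12, q, d)
    expect_equal(vt2$viterbi, vt$viterbi)
  }
  # uniform likelihoods: constant path at argmax q; exact ties -> lowest
  llu <- matrix(0, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  vt <- viterbi_decode(llu, 5, c(0.2, 0.6, 0.2), rep(0.1, 3))
  expect_equal(unique(vt$viterbi), "b")
  vt_tie <- viterbi_decode(llu, 5, rep(1 / 3, 3), rep(0.1, 3))
  expect_equal(unique(vt_tie$viterbi), "a")
})

test_that("Viterbi path likelihood dominates truth and random paths", {
  set.seed(10)
  W <- 12; K <- 3
  loglik <- matrix(rnorm(W * K, sd = 1.5), W, K)
  q <- rep(1 / 3, 3)
  d <- runif(W - 1, 0.05, 0.2)
  g <- 8
  path_ll <- function(pp) {
    lp <- log(q[pp[1]]) + loglik[1, pp[1]]
    for (w in 2:W) {
      P <- transition_matrix(g, d[w - 1], q)
      lp <- lp + log(P[pp[w - 1], pp[w]]) + loglik[w, pp[w]]
    }
    lp
  }
  vt <- viterbi_decode(loglik, g, q, d)
  vll <- path_ll(match(vt$viterbi, as.character(1:K)))
  for (i in 1:20) expect_lte(path_ll(sample(1:K, W, TRUE)), vll + 1e-12)
})

test_that("generations parameter is recovered within a factor of two", {
  setup <- make_two_pop_setup(seed = 13, n_variants = 1400)
  mod <- migration_model(8, c(A = 0.5, B = 0.5), N = 400)
  coh <- simulate_admixed_cohort(mod, setup$anc_model, setup$map,
                                 n_samples = 12, seed = 14)
  wm <- fit_window_model(setup$refs, window_size = 70)
  dists <- admixkit:::window_distances(wm)
  logliks <- lapply(seq_len(24), function(i) {
    window_loglikelihoods(coh$panel$alleles[i, ], wm)
  })
  q <- c(0.5, 0.5)
  g <- optimize_generations(logliks, q, dists)
  expect_gte(as.numeric(g), 4)
  expect_lte(as.numeric(g), 16)
  # local optimality of the summed likelihood
  ll_at <- function(gg) sum(vapply(logliks, forward_loglik, 1.0, g = gg,
                                   q = q, distances = dists))
  expect_gte(ll_at(as.numeric(g)) + 1e-6, ll_at(as.numeric(g) / 2))
  expect_gte(ll_at(as.numeric(g)) + 1e-6, ll_at(as.numeric(g) * 2))
  # flat likelihood: bound + warning
  flat <- list(matrix(0, 5, 2))
  expect_warning(gf <- optimize_generations(flat, q, rep(0.1, 4)),
                 "bound")
  expect_error(optimize_generations(list(), q, dists), "no haplotypes")
})

test_that("window calls merge into boundary-correct tracts", {
  setup <- make_two_pop_setup(seed = 15, n_variants = 350)
  wm <- fit_window_model(setup$refs, window_size = 70)  # 5 windows
  labels <- c("A", "A", "B", "B", "B")
  tr <- calls_to_tracts(labels, wm, hap_id = "h1")
  expect_equal(nrow(tr), 2L)
  v <- setup$variants
  info <- wm$window_info
  cut_cm <- (v$pos_cM[info$last_idx[2]] + v$pos_cM[info$first_idx[3]]) / 2
  expect_equal(tr$end_cM[1], cut_cm)
  expect_equal(tr$start_cM[2], cut_cm)
  expect_equal(tr$ancestry, c("A", "B"))
  expect_false(any(tr$is_whole_chromosome))

  tr1 <- calls_to_tracts(rep("A", 5), wm, hap_id = "h1")
  expect_equal(nrow(tr1), 1L)
  expect_true(tr1$is_whole_chromosome)
})

test_that("painting accuracy exceeds 90% of sites at divergence 0.1+", {
  acc_at <- function(F_div, seed = 7) {
    setup <- make_two_pop_setup(seed = seed, n_variants = 1400,
                                F_div = F_div)
    mod <- migration_model(6, c(A = 0.5, B = 0.5), N = 400)
    coh <- simulate_admixed_cohort(mod, setup$anc_model, setup$map,
                                   n_samples = 10,
                                   seed = child_seed(seed, "coh"))
    wm <- fit_window_model(setup$refs, window_size = 70)
    pt <- infer_local_ancestry(coh$panel, wm)
    accs <- vapply(coh$panel$haplotypes$hap_id, function(hid) {
      cc <- pt$calls[pt$calls$hap_id == hid, ]
      cc <- cc[order(cc$window), ]
      lab_site <- rep(cc$viterbi, wm$window_info$last_idx -
                        wm$window_info$first_idx + 1)
      tt <- coh$truth[coh$truth$hap_id == hid, ]
      tl <- tt$ancestry[findInterval(setup$variants$pos_cM,
                                     c(tt$start_cM[1], tt$end_cM),
                                     rightmost.closed = TRUE)]
      mean(lab_site == tl)
    }, 1.0)
    mean(accs)
  }
  a_lo <- acc_at(0.05)
  a_hi <- acc_at(0.2)
  a_mid <- acc_at(0.1)
  expect_gte(a_mid, 0.9)
  # accuracy increases with ancestral divergence
  expect_gt(a_mid, a_lo)
  expect_gt(a_hi, a_mid)
})

test_that("disjoint block HMMs deconvolve sub-ancestry within tracts", {
  set.seed(20)
  setup <- make_two_pop_setup(seed = 21, n_variants = 2100, F_div = 0.05,
                              n_ref_haps = 60)
  # a haplotype truly from sub-population A across two blocks
  hapA <- simulate_reference_haplotypes(setup$freqs$A, 2, setup$variants,
                                        population = "A", seed = 22)
  blocks <- tract_set(
    hap_id = c("x_0", "x_0"), chrom = c("1", "1"),
    start_bp = c(1, 9e6), end_bp = c(8e6, 19e6),
    start_cM = c(0, 90), end_cM = c(80, 190),
    ancestry = c("AFR", "AFR")
  )
  post <- deconvolve_within_tracts(hapA$alleles[1, ], blocks, setup$refs,
                                   window_size = 70, g = 5)
  expect_setequal(unique(post$block), c(1L, 2L))
  expect_gt(mean(post$A), 0.9)
  # no information flows across blocks: posteriors per block match a run
  # on that block alone
  post1 <- deconvolve_within_tracts(hapA$alleles[1, ], blocks[1, ],
                                    setup$refs, window_size = 70, g = 5)
  expect_equal(post$A[post$block == 1], post1$A, tolerance = 1e-12)

  # identical sub-reference pops: posteriors ~ 0.5
  labels2 <- setup$refs$labels
  idx <- order(labels2$sample_id)
  pooled <- simulate_reference_haplotypes(setup$freqs$A, 40,
                                          setup$variants,
                                          population = "A", seed = 23)
  lab <- pooled$labels
  lab$population <- rep(c("A", "B"), 10)
  same <- haplotype_panel(pooled$alleles, setup$variants, lab)
  post_same <- deconvolve_within_tracts(hapA$alleles[1, ], blocks[1, ],
                                        same, window_size = 70, g = 5)
  expect_lt(max(abs(post_same$A - 0.5)), 0.45)
  expect_lt(abs(mean(post_same$A) - 0.5), 0.25)

  # block shorter than one window -> skipped with warning
  shortb <- tract_set("x_0", "1", 1, 2e5, 0, 2, "AFR")
  expect_warning(
    ps <- deconvolve_within_tracts(hapA$alleles[1, ], shortb, setup$refs,
                                   window_size = 70, g = 5),
    "skipped"
  )
  expect_equal(nrow(ps), 0L)
})

test_that("confident sub-ancestry fractions stratify by block size", {
  bp <- tibble::tibble(
    block = rep(1:4, each = 5), window = rep(1:5, 4),
    block_length_cM = rep(c(2, 4, 20, 40), each = 5),
    n_windows = 5L,
    A = c(rep(0.99, 10), rep(0.99, 2), rep(0.01, 8)),
    B = 1 - c(rep(0.99, 10), rep(0.99, 2), rep(0.01, 8))
  )
  out <- subancestry_fraction_by_block_size(bp, "A", "B",
                                            breaks = c(0, 5, 50))
  expect_equal(out$fraction[1], 1)             # all short blocks pure A
  expect_equal(out$fraction[2], 0.2)
  expect_equal(out$n_windows, c(10L, 10L))
  # impossible confidence empties the bins
  out2 <- subancestry_fraction_by_block_size(bp, "A", "B",
                                             breaks = c(0, 5, 50),
                                             confidence = 1)
  expect_true(all(is.na(out2$fraction)))
  expect_equal(out2$n_windows, c(0L, 0L))
})
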