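# Tract-length histogramming, the expected-count engine, Poisson
# likelihood, model fitting and BIC selection.

test_that("binning yields 51 bins per ancestry and conserves counts", {
  set.seed(50)
  tr <- tract_set(
    hap_id = rep(paste0("h", 1:10, "_0"), each = 3),
    chrom = "1",
    start_bp = rep(c(1, 4e7, 8e7), 10),
    end_bp = rep(c(4e7, 8e7, 1e8), 10),
    start_cM = rep(c(0, 60, 130), 10),
    end_cM = rep(c(60, 130, 180), 10),
    ancestry = sample(c("EUR", "NAT", "AFR"), 30, TRUE)
  )
  hist <- bin_tract_lengths(tr, c(chr1 = 1.8), n_bins = 50,
                            ancestries = c("AFR", "EUR", "NAT"))
  expect_equal(dim(hist$counts), c(3L, 51L))
  expect_equal(length(hist$counts), 153L)  # 3 ancestries x 51 bins
  expect_equal(sum(hist$counts), 30)       # counts conserve tract count
  # whole-chromosome flag beats length
  tr2 <- tr[1, ]
  tr2$is_whole_chromosome <- TRUE
  tr2$end_cM <- tr2$start_cM + 1   # shorter than one bin width
  tr2$length_cM <- 1
  h2 <- bin_tract_lengths(tr2, c(chr1 = 1.8), n_bins = 50)
  expect_equal(unname(h2$counts[1, 51]), 1L)
  expect_equal(sum(h2$counts[, 1:50]), 0L)
  # an over-long unflagged tract is inconsistent input
  tr3 <- tr[1, ]
  tr3$end_cM <- tr3$start_cM + 500
  tr3$length_cM <- 500
  expect_error(bin_tract_lengths(tr3, c(chr1 = 1.8)), "whole")
})

test_that("single-ancestry model puts all mass in the whole-chromosome bin", {
  eh <- expected_histogram(migration_model(12, c(A = 1)), c(c1 = 2.5),
                           n_haplotypes = 7)
  expect_equal(unname(eh$counts["A", 51]), 7, tolerance = 1e-9)
  expect_equal(sum(eh$counts["A", 1:50]), 0, tolerance = 1e-9)
})

test_that("expected ancestry mass equals the trajectory proportions", {
  mod <- migration_model(
    16, c(EUR = 0.3, NAT = 0.7),
    tibble::tibble(time = c(10, 4), source = c("AFR", "EUR"),
                   magnitude = c(0.2, 0.15))
  )
  gen <- admixkit:::tract_process_generator(mod)
  pi_frac <- tapply(gen$pi, gen$states$ancestry, sum)
  expect_equal(sum(gen$pi), 1, tolerance = 1e-12)
  traj <- present_proportions(mod)
  for (a in names(traj)) {
    expect_equal(unname(pi_frac[a]), unname(traj[a]), tolerance = 1e-9)
  }
})

test_that("expected histograms agree with the Monte Carlo painting oracle", {
  # single pulse: mean minority tract length within 5% of MC at n=20000
  mod <- migration_model(10, c(A = 0.2, B = 0.8))
  eh <- expected_histogram(mod, c(c1 = 10), n_haplotypes = 1, n_bins = 400)
  mid <- (head(eh$bin_edges, -1) + eh$bin_edges[-1]) / 2
  meanA_engine <- sum(eh$counts["A", 1:400] * mid) /
    sum(eh$counts["A", 1:400])
  mc <- simulate_tract_painting_mc(mod, 10, 20000, seed = 51)
  lens <- mc$length_M[mc$ancestry == "A" & !mc$is_whole_chromosome]
  expect_lt(abs(meanA_engine - mean(lens)) / mean(lens), 0.05)
  # total counts agree too
  expect_lt(abs(sum(eh$counts["A", ]) -
                  sum(mc$ancestry == "A") / 20000) /
              (sum(mc$ancestry == "A") / 20000), 0.05)
})

test_that("engine matches Monte Carlo bin-by-bin for all three structures", {
  structures <- list(
    migration_model(12, c(EUR = 0.4, NAT = 0.6),
                    tibble::tibble(time = 8, source = "AFR",
                                   magnitude = 0.25)),
    migration_model(12, c(EUR = 0.4, NAT = 0.6),
                    tibble::tibble(time = c(8, 4), source = c("AFR", "EUR"),
                                   magnitude = c(0.25, 0.3))),
    migration_model(12, c(EUR = 0.4, NAT = 0.6),
                    tibble::tibble(time = c(8, 4), source = c("AFR", "AFR"),
                                   magnitude = c(0.25, 0.2)))
  )
  n_mc <- 6000
  for (si in seq_along(structures)) {
    mod <- structures[[si]]
    C <- 2.0
    eh <- expected_histogram(mod, c(c1 = C), n_haplotypes = n_mc,
                             n_bins = 50)
    mc <- simulate_tract_painting_mc(mod, C, n_mc,
                                     seed = child_seed(52, paste(si)))
    mc_tr <- tibble::tibble(
      hap_id = paste0("p", mc$painting, "_0"), chrom = "c1",
      start_cM = 0, end_cM = mc$length_M * 100,
      start_bp = 1, end_bp = 2,
      ancestry = mc$ancestry,
      is_whole_chromosome = mc$is_whole_chromosome,
      length_cM = mc$length_M * 100
    )
    oh <- bin_tract_lengths(mc_tr, c(c1 = C), n_bins = 50,
                            ancestries = rownames(eh$counts))
    # aggregated chi-square over bins with non-trivial expectation
    e <- as.vector(eh$counts)
    o <- as.vector(oh$counts)
    keep <- e >= 5
    chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
    dof <- sum(keep)
    expect_lt(chi2, qchisq(0.99, dof))
    # no gross per-bin discrepancy (5 Poisson SE guards against a wrong
    # bin; individual 3-SE excursions are expected across ~100 bins)
    expect_true(all(abs(o[keep] - e[keep]) <= 5 * sqrt(e[keep]) + 5))
  }
})

test_that("engine log-abundance is linear for one pulse, curved for two", {
  eh1 <- expected_histogram(
    migration_model(12, c(A = 0.35, B = 0.65)), c(c1 = 6),
    n_haplotypes = 800, n_bins = 60
  )
  mid <- (head(eh1$bin_edges, -1) + eh1$bin_edges[-1]) / 2
  keep <- mid <= 1.2
  c1 <- eh1$counts["A", 1:60]
  df1 <- data.frame(x = mid[keep], y = log(c1[keep]))
  lin <- lm(y ~ x, df1, weights = c1[keep])
  expect_gt(summary(lin)$r.squared, 0.99)
  quad1 <- coef(lm(y ~ x + I(x^2), df1, weights = c1[keep]))[3]

  eh2 <- expected_histogram(
    migration_model(12, c(A = 0.2, B = 0.8),
                    tibble::tibble(time = 3, source = "A",
                                   magnitude = 0.25)),
    c(c1 = 6), n_haplotypes = 800, n_bins = 60
  )
  c2 <- eh2$counts["A", 1:60]
  keep2 <- c2 > 1
  df2 <- data.frame(x = mid[keep2], y = log(c2[keep2]))
  quad2 <- coef(lm(y ~ x + I(x^2), df2, weights = c2[keep2]))[3]
  expect_lt(abs(quad1), 0.05)              # straight line
  expect_gt(quad2, 1)                      # strong curvature
})

test_that("Poisson log-likelihood matches hand arithmetic and its MLE", {
  expect_equal(poisson_loglikelihood(2, 2), 2 * log(2) - 2 - log(2),
               tolerance = 1e-12)
  expect_equal(poisson_loglikelihood(2, 2), -1.3069, tolerance = 1e-4)
  o <- c(3, 0, 7, 1)
  ll_at_o <- poisson_loglikelihood(o, o)
  for (i in 1:20) {
    e <- pmax(o + rnorm(4, sd = 0.5), 0.01)
    expect_lte(poisson_loglikelihood(o, e), ll_at_o)
  }
  expect_equal(poisson_loglikelihood(0, 1e-9), -1e-9, tolerance = 1e-12)
  expect_error(poisson_loglikelihood(-1, 1), "negative")
})

test_that("BIC selection reproduces the printed arithmetic and tie rule", {
  fake_fit <- function(ll, k, tag) {
    structure(list(structure = tag, loglik = ll, k = k, n = 153,
                   bic = -2 * ll + k * log(153)),
              class = "tracts_fit")
  }
  f <- fake_fit(-139.22, 6, "m2")
  expect_equal(f$bic, 278.44 + 6 * log(153), tolerance = 1e-12)
  expect_equal(f$bic, 308.62, tolerance = 0.01)
  # three-way selection on log-likelihoods with k = (4, 6, 6):
  # the third model wins on BIC
  fits <- list(fake_fit(-506.43, 4, "simple"),
               fake_fit(-497.62, 6, "plus_eur"),
               fake_fit(-326.12, 6, "plus_afr"))
  best <- bic_select(fits)
  expect_equal(best$structure, "plus_afr")
  tb <- attr(best, "bic_table")
  expect_equal(tb$bic, c(1033.0, 1025.4, 682.4), tolerance = 0.05)
  # equal log-likelihoods: fewer parameters win
  tie <- bic_select(list(fake_fit(-100, 6, "big"), fake_fit(-100, 4, "small")))
  expect_equal(tie$structure, "small")
  expect_error(bic_select(list(f)), "at least two")
})

test_that("migration-model fits recover simulated parameters", {
  # simulate tracts under a simple founding + AFR pulse, fit the same
  # structure, and check the recovered founding time
  chroms <- setNames(c(2.8, 2.2, 1.8), paste0("c", 1:3))
  mod <- migration_model(16, c(EUR = 0.3, NAT = 0.7),
                         tibble::tibble(time = 10, source = "AFR",
                                        magnitude = 0.2))
  gen_tracts <- function(seed) {
    out <- list()
    for (ci in seq_along(chroms)) {
      mc <- simulate_tract_painting_mc(mod, chroms[ci], 400,
                                       seed = child_seed(seed, names(chroms)[ci]))
      out[[ci]] <- tibble::tibble(
        hap_id = paste0("h", mc$painting, "_0"),
        chrom = names(chroms)[ci],
        start_cM = 0, end_cM = mc$length_M * 100, start_bp = 1,
        end_bp = 2, ancestry = mc$ancestry,
        is_whole_chromosome = mc$is_whole_chromosome,
        length_cM = mc$length_M * 100
      )
    }
    dplyr::bind_rows(out)
  }
  hist <- bin_tract_lengths(gen_tracts(60), chroms,
                            ancestries = c("AFR", "EUR", "NAT"))
  fit <- fit_migration_model(hist, "EUR,NAT+AFR", n_restarts = 4,
                             seed = 61)
  expect_true(fit$converged)
  expect_equal(fit$k, 4L)
  expect_lt(abs(fit$model$T1 - 16), 2.5)
  expect_lt(abs(fit$model$founding["EUR"] - 0.3), 0.08)
  # nesting: the extra-pulse model can only improve the likelihood
  fit2 <- fit_migration_model(hist, "EUR,NAT+AFR+AFR", n_restarts = 4,
                              seed = 62)
  expect_gte(fit2$loglik, fit$loglik - 0.5)
  expect_equal(fit2$k, 6L)
  # determinism under a fixed seed
  refit <- fit_migration_model(hist, "EUR,NAT+AFR", n_restarts = 4,
                               seed = 61)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(refit$model$T1, fit$model$T1, tolerance = 1e-9)
})

test_that("fit results expose tidy() parameters and glance() summaries", {
  chroms <- c(c1 = 2.0)
  mod <- migration_model(10, c(EUR = 0.4, NAT = 0.6),
                         tibble::tibble(time = 6, source = "AFR",
                                        magnitude = 0.25))
  mc <- simulate_tract_painting_mc(mod, 2.0, 300, seed = 63)
  tr <- tibble::tibble(
    hap_id = paste0("h", mc$painting, "_0"), chrom = "c1",
    start_cM = 0, end_cM = mc$length_M * 100, start_bp = 1, end_bp = 2,
    ancestry = mc$ancestry, is_whole_chromosome = mc$is_whole_chromosome,
    length_cM = mc$length_M * 100
  )
  hist <- bin_tract_lengths(tr, chroms, ancestries = c("AFR", "EUR", "NAT"))
  fit <- fit_migration_model(hist, "EUR,NAT+AFR", n_restarts = 2, seed = 64)
  td <- tidy(fit)
  expect_setequal(td$parameter, c("T1", "p_EUR", "T2", "m_AFR"))
  gl <- glance(fit)
  expect_equal(gl$k, 4L)
  expect_equal(gl$BIC, -2 * fit$loglik + 4 * log(153), tolerance = 1e-9)
  # present-day proportions delegate to the trajectory recursion
  props <- model_final_proportions(fit)
  expect_equal(sum(props), 1, tolerance = 1e-9)
})

test_that("final proportions reproduce the two-pulse arithmetic", {
  m <- (0.75 - 0.125) / (1 - 0.125)
  mod <- migration_model(14, c(EUR = 0.125, NAT = 0.875),
                         tibble::tibble(time = 12, source = "EUR",
                                        magnitude = m))
  fit <- structure(list(model = mod), class = "tracts_fit")
  props <- model_final_proportions(fit)
  expect_equal(unname(props["EUR"]), 0.75, tolerance = 1e-9)
  # no pulses: founding proportions unchanged
  fit0 <- structure(list(model = migration_model(9, c(A = 0.6, B = 0.4))),
                    class = "tracts_fit")
  expect_equal(unname(model_final_proportions(fit0)), c(0.6, 0.4),
               tolerance = 1e-12)
})
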