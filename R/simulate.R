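# Synthetic data generation: Balding-Nichols founder populations, forward
# admixture simulation with ground-truth paintings, and parent-pair
# ancestry tables.

#' Deterministic child seed derived from a master seed
#'
#' Simulation components derive their own seeds from one master seed so
#' that sub-steps are reproducible independently. Kept below 2^31.
#'
#' @param seed Master seed (integer).
#' @param component Character tag of the component.
#' @return An integer seed.
#' @export
child_seed <- function(seed, component) {
  p <- 2147483629
  h <- 0
  for (b in utf8ToInt(component)) h <- (h * 131 + b) %% p
  x <- as.numeric(seed) %% p
  for (i in 1:3) x <- (x * 48271 + h + i) %% p
  as.integer(x %% (p - 1)) + 1L
}

#' Draw sub-population allele frequencies (Balding-Nichols)
#'
#' Given ancestral frequencies `p` and divergence `F`, draws each
#' sub-population frequency independently from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)`, whose mean is `p` and variance
#' `F p (1-p)`.
#'
#' @param p Base allele frequency vector, all in (0, 1).
#' @param F_div Divergence parameter in (0, 1).
#' @param seed Optional seed for reproducibility.
#' @return Frequency vector of the same length, clamped away from 0/1 by
#'   1e-9.
#' @export
draw_subpopulation_frequencies <- function(p, F_div, seed = NULL) {
  if (F_div <= 0 || F_div >= 1) stop("F_div must lie strictly in (0, 1)")
  if (any(p <= 0 | p >= 1)) stop("base frequencies must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  q <- rbeta(length(p), p * (1 - F_div) / F_div,
             (1 - p) * (1 - F_div) / F_div)
  pmin(pmax(q, 1e-9), 1 - 1e-9)
}

#' Simulate reference haplotypes from allele frequencies
#'
#' Independent Bernoulli(freq) alleles per site per haplotype (linkage
#' equilibrium within the reference population).
#'
#' @param freqs Allele frequency vector in (0, 1).
#' @param n_haplotypes Number of haplotypes (must be even: two per sample).
#' @param variants Optional [variant_table()] with `length(freqs)` rows;
#'   defaults to evenly spaced positions on chromosome "1".
#' @param population Population label.
#' @param prefix Sample id prefix.
#' @param seed Optional seed.
#' @return A [haplotype_panel()].
#' @export
simulate_reference_haplotypes <- function(freqs, n_haplotypes,
                                          variants = NULL,
                                          population = "ref",
                                          prefix = population,
                                          seed = NULL) {
  if (n_haplotypes <= 0) stop("n_haplotypes must be positive")
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even")
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  if (is.null(variants)) {
    variants <- variant_table(chrom = "1", pos_bp = seq_len(L) * 1000L,
                              pos_cM = seq_len(L) * 0.1)
  }
  stopifnot(nrow(variants) == L)
  alleles <- matrix(rbinom(n_haplotypes * L, 1L, rep(freqs, each = n_haplotypes)),
                    nrow = n_haplotypes, ncol = L)
  n_samp <- n_haplotypes / 2
  ids <- paste0(prefix, seq_len(n_samp))
  rownames(alleles) <- paste0(rep(ids, each = 2), "_", c(0L, 1L))
  haplotype_panel(alleles, variants,
                  tibble::tibble(sample_id = ids, population = population))
}

#' Ancestral population model for the simulator
#'
#' Holds per-ancestry allele frequencies for a common variant set; the
#' forward simulator paints alleles from these frequencies according to
#' each haplotype's true local ancestry.
#'
#' @param freqs Named list of frequency vectors (one per ancestry, equal
#'   lengths, all in (0, 1)).
#' @param variants A [variant_table()] with matching row count.
#' @return Object of class `ancestral_population_model`.
#' @export
ancestral_population_model <- function(freqs, variants) {
  stopifnot(is.list(freqs), !is.null(names(freqs)))
  L <- unique(vapply(freqs, length, 1L))
  if (length(L) != 1 || L != nrow(variants)) {
    stop("all frequency vectors must match the variant count")
  }
  lapply(freqs, function(p) {
    if (any(p <= 0 | p >= 1)) stop("frequencies must lie in (0, 1)")
  })
  structure(list(freqs = freqs, variants = variants),
            class = "ancestral_population_model")
}

#' Evenly spaced variants along a genetic map
#'
#' Convenience generator used by the simulator: places `n` variants per
#' chromosome uniformly in genetic distance, with bp positions from linear
#' inverse interpolation of the map.
#'
#' @param map A [genetic_map()].
#' @param n_per_chrom Number of variants per chromosome.
#' @return A [variant_table()].
#' @export
uniform_variants <- function(map, n_per_chrom) {
  out <- lapply(split(map, map$chrom), function(knots) {
    cm <- seq(min(knots$pos_cM), max(knots$pos_cM),
              length.out = n_per_chrom + 2)[-c(1, n_per_chrom + 2)]
    bp <- if (nrow(knots) == 1) rep(knots$pos_bp, length(cm)) else {
      approx(knots$pos_cM, knots$pos_bp, xout = cm, rule = 2,
             ties = "ordered")$y
    }
    tibble::tibble(chrom = knots$chrom[1], pos_bp = as.integer(round(bp)),
                   pos_cM = cm)
  })
  tb <- dplyr::bind_rows(out)
  # guarantee strictly increasing bp within chromosome
  tb <- tb |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(pos_bp = .data$pos_bp +
                    cumsum(c(0L, as.integer(diff(.data$pos_bp) <= 0)))) |>
    dplyr::ungroup()
  variant_table(tb$chrom, tb$pos_bp, tb$pos_cM)
}

chrom_lengths_morgans <- function(map) {
  map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(start_cM = min(.data$pos_cM), end_cM = max(.data$pos_cM),
                     .groups = "drop") |>
    dplyr::mutate(length_M = (.data$end_cM - .data$start_cM) / 100)
}

#' Simulate an admixed cohort with ground-truth ancestry paintings
#'
#' Forward simulation: at the founding generation, `2N` haplotypes are
#' labelled by the founding proportions; every later generation each
#' haplotype is a recombinant of two randomly chosen previous-generation
#' haplotypes, with a Poisson (chromosome length in Morgans) number of
#' crossovers placed uniformly in genetic distance. At pulse times, a
#' fraction of individuals is replaced by unadmixed source individuals.
#' Finally `n_samples` individuals are drawn without replacement, their
#' paintings recorded as the truth tract set, and alleles painted from the
#' per-ancestry frequencies.
#'
#' @param model A [migration_model()] (integer times; fractional times are
#'   discretized as for the likelihood engine).
#' @param anc_model An [ancestral_population_model()] whose ancestries
#'   cover the model's.
#' @param map A [genetic_map()] providing chromosome extents.
#' @param n_samples Number of diploid samples to draw.
#' @param seed Master seed.
#' @param population Cohort population label.
#' @return A list of class `simulated_cohort` with elements `panel`
#'   ([haplotype_panel()]), `truth` ([tract_set()] tibble), `model`, `seed`.
#' @export
simulate_admixed_cohort <- function(model, anc_model, map, n_samples,
                                    seed = 1L, population = "admixed") {
  if (2 * model$N < 2 * n_samples) {
    stop("population size 2N too small for requested sample")
  }
  variants <- anc_model$variants
  stopifnot(all(unique(variants$chrom) %in% unique(map$chrom)))
  miss_anc <- setdiff(model$ancestries, names(anc_model$freqs))
  if (length(miss_anc)) {
    stop("no allele frequencies for ancestry: ",
         paste(miss_anc, collapse = ", "))
  }
  d <- discretize_migration_model(model)
  anc <- d$ancestries
  founding_ev <- which(d$mag >= 1)[1]
  T1_int <- d$time[founding_ev]
  fvec <- d$src[founding_ev, ]
  later <- setdiff(seq_along(d$time), founding_ev)
  chrlen <- chrom_lengths_morgans(map)
  chrlen <- chrlen[chrlen$chrom %in% unique(variants$chrom), ]

  ids <- paste0(population, seq_len(n_samples))
  hap_ids <- paste0(rep(ids, each = 2), "_", c(0L, 1L))
  tracts <- list()
  alleles <- matrix(NA_integer_, nrow = 2 * n_samples, ncol = nrow(variants),
                    dimnames = list(hap_ids, NULL))
  freq_mat <- do.call(rbind, anc_model$freqs[anc]) # K x L

  set.seed(child_seed(seed, "forward-paint"))
  for (ci in seq_len(nrow(chrlen))) {
    chr <- chrlen$chrom[ci]
    Lm <- chrlen$length_M[ci]
    res <- forward_paint_chr(
      N = model$N, T1 = T1_int, founding = unname(fvec),
      pulse_time = as.integer(d$time[later]),
      pulse_source = unname(d$src[later, , drop = FALSE]),
      pulse_mag = d$mag[later], L = Lm, n_keep_ind = n_samples
    )
    vidx <- which(variants$chrom == chr)
    v_cm <- variants$pos_cM[vidx]
    cm0 <- chrlen$start_cM[ci]
    knots <- map[map$chrom == chr, ]
    # accumulate tract fields as flat vectors (one tibble per chromosome)
    nsegs <- vapply(res, function(pt) length(pt$labels), 1L)
    all_edges_cm <- lapply(res, function(pt) cm0 + c(0, pt$breaks, Lm) * 100)
    edge_vec <- unlist(all_edges_cm)
    bp_vec <- if (nrow(knots) == 1) rep(knots$pos_bp, length(edge_vec)) else {
      approx(knots$pos_cM, knots$pos_bp, xout = edge_vec, rule = 2,
             ties = "ordered")$y
    }
    starts <- ends <- bp_s <- bp_e <- vector("list", length(res))
    off <- 0
    for (h in seq_along(res)) {
      ne <- nsegs[h] + 1
      e_cm <- edge_vec[(off + 1):(off + ne)]
      e_bp <- bp_vec[(off + 1):(off + ne)]
      starts[[h]] <- e_cm[-ne]; ends[[h]] <- e_cm[-1]
      bp_s[[h]] <- e_bp[-ne]; bp_e[[h]] <- e_bp[-1]
      off <- off + ne
    }
    tracts[[length(tracts) + 1]] <- tibble::tibble(
      hap_id = rep(hap_ids, nsegs), chrom = chr,
      start_cM = unlist(starts), end_cM = unlist(ends),
      start_bp = unlist(bp_s), end_bp = unlist(bp_e),
      ancestry = anc[unlist(lapply(res, function(pt) pt$labels)) + 1L],
      is_whole_chromosome = rep(nsegs == 1, nsegs)
    )
    # paint alleles
    for (h in seq_along(res)) {
      pt <- res[[h]]
      seg_of_var <- findInterval((v_cm - cm0) / 100, c(0, pt$breaks),
                                 rightmost.closed = FALSE)
      seg_of_var[seg_of_var < 1] <- 1L
      lab_idx <- pt$labels[seg_of_var] + 1L
      pvar <- freq_mat[cbind(lab_idx, vidx)]
      alleles[h, vidx] <- as.integer(runif(length(vidx)) < pvar)
    }
  }
  truth <- dplyr::bind_rows(tracts) |>
    dplyr::mutate(length_cM = .data$end_cM - .data$start_cM)
  # bp edges can tie on flat map stretches; nudge to keep end > start
  truth$end_bp <- pmax(truth$end_bp, truth$start_bp + 1)
  panel <- haplotype_panel(
    alleles, variants,
    tibble::tibble(sample_id = ids, population = population)
  )
  structure(list(panel = panel, truth = truth, model = model, seed = seed),
            class = "simulated_cohort")
}

#' @exportS3Method base::print
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", nrow(x$panel$alleles), " haplotypes, ",
      nrow(x$truth), " truth tracts\n", sep = "")
  invisible(x)
}

#' Simulate parent-pair ancestry tables
#'
#' Gaussian-copula construction: maternal and paternal values of a chosen
#' ancestry component are Beta-distributed marginals linked by a bivariate
#' normal copula with correlation `target_correlation`; the remaining mass
#' is split between the other two ancestries by an independent Beta draw.
#' X-chromosome proportions are the autosomal proportions shifted toward
#' `bias_ancestry` by `sex_bias` and re-normalised:
#' `p_X = (p + sex_bias * e_a) / (1 + sex_bias)`.
#'
#' @param n_pairs Number of parent pairs.
#' @param target_correlation Desired Pearson correlation of the first
#'   ancestry component between mates, in \[-1, 1\].
#' @param sex_bias Non-negative shift of X proportions toward
#'   `bias_ancestry` (0 = X identical to autosomes).
#' @param ancestries Three ancestry names; the first is the correlated
#'   component.
#' @param bias_ancestry Ancestry receiving the X shift.
#' @param shape Beta marginal shape parameters `c(a, b)` of the correlated
#'   component.
#' @param seed Optional seed.
#' @return Tibble with one row per parent (columns `pair_id`, `role`,
#'   `sex`, one column per ancestry, and `<ancestry>_X` columns).
#' @export
simulate_parent_pairs <- function(n_pairs, target_correlation = 0,
                                  sex_bias = 0,
                                  ancestries = c("NAT", "EUR", "AFR"),
                                  bias_ancestry = ancestries[1],
                                  shape = c(2, 4), seed = NULL) {
  if (abs(target_correlation) > 1) stop("target_correlation must be in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(ancestries) == 3, bias_ancestry %in% ancestries)
  rho <- target_correlation
  z_m <- rnorm(n_pairs)
  z_p <- rho * z_m + sqrt(1 - rho^2) * rnorm(n_pairs)
  x_m <- qbeta(pnorm(z_m), shape[1], shape[2])
  x_p <- qbeta(pnorm(z_p), shape[1], shape[2])
  split_m <- rbeta(n_pairs, 2, 2)
  split_p <- rbeta(n_pairs, 2, 2)
  build <- function(x, split, role) {
    m <- cbind(x, (1 - x) * split, (1 - x) * (1 - split))
    colnames(m) <- ancestries
    tb <- tibble::as_tibble(m)
    tb$pair_id <- paste0("fam", seq_len(n_pairs))
    tb$role <- role
    tb$sex <- if (role == "mother") "F" else "M"
    tb
  }
  out <- dplyr::bind_rows(build(x_m, split_m, "mother"),
                          build(x_p, split_p, "father"))
  e_a <- as.numeric(ancestries == bias_ancestry)
  xmat <- as.matrix(out[, ancestries])
  xshift <- sweep(xmat, 2, e_a * sex_bias, "+") / (1 + sex_bias)
  colnames(xshift) <- paste0(ancestries, "_X")
  dplyr::bind_cols(
    out[, c("pair_id", "role", "sex", ancestries)],
    tibble::as_tibble(xshift)
  )
}
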