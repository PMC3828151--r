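# Cohort-level statistics: X-vs-autosome ancestry bias, assortative
# mating, summed pairwise IBD, allele-frequency FST, and generation/year
# conversions.

#' X-vs-autosome ancestry bias test
#'
#' Wilcoxon signed-rank test on the paired per-individual differences
#' between X-chromosome and autosomal proportions of one ancestry,
#' restricted to females (a diploid X compares like-for-like with diploid
#' autosomes). Zero differences are dropped (Wilcoxon convention, count
#' reported); exact null for n <= 25 without ties, normal approximation
#' otherwise. The test is two-sided and does not by itself say which
#' proportion is larger, so the median difference is reported alongside.
#'
#' @param table Tibble with columns `sex`, `<ancestry>` (autosomal
#'   proportion) and `<ancestry>_X`.
#' @param ancestry Ancestry column to test.
#' @param alternative Test sidedness (default `"two.sided"`).
#' @return List: `median_difference`, `p_value`, `n_used`,
#'   `n_zero_dropped`, `degenerate`.
#' @export
x_autosome_bias_test <- function(table, ancestry,
                                 alternative = "two.sided") {
  xcol <- paste0(ancestry, "_X")
  stopifnot(all(c("sex", ancestry, xcol) %in% names(table)))
  f <- table[table$sex == "F", ]
  if (nrow(f) < 6) stop("need >= 6 females with X and autosomal values")
  d <- f[[xcol]] - f[[ancestry]]
  med <- median(d)
  nz <- d[d != 0]
  dropped <- length(d) - length(nz)
  if (dropped) message(dropped, " zero difference(s) dropped")
  if (!length(nz)) {
    return(list(median_difference = med, p_value = 1,
                n_used = 0L, n_zero_dropped = dropped, degenerate = TRUE))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = alternative, exact = exact,
                correct = !exact)
  )
  list(median_difference = med, p_value = ht$p.value,
       n_used = length(nz), n_zero_dropped = dropped, degenerate = FALSE)
}

#' Assortative-mating permutation test
#'
#' Pearson correlation of maternal and paternal proportions of one
#' ancestry across parent pairs, with a permutation null built by
#' re-pairing fathers at random (globally, or within population labels to
#' control for population structure). One-sided
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param pairs Tibble from [simulate_parent_pairs()] or with columns
#'   `pair_id`, `role` (`"mother"`/`"father"`), the ancestry column, and
#'   optionally `population`.
#' @param ancestry Ancestry column to correlate.
#' @param n_perm Number of permutations (default 100000).
#' @param within_groups Permute within `population` labels.
#' @param seed Optional seed.
#' @return List: `r`, `p_value`, `n_pairs`.
#' @export
mating_correlation_test <- function(pairs, ancestry, n_perm = 100000,
                                    within_groups = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- pairs[pairs$role == "mother", ]
  p <- pairs[pairs$role == "father", ]
  p <- p[match(m$pair_id, p$pair_id), ]
  n <- nrow(m)
  if (n < 3) stop("need at least 3 parent pairs")
  x <- m[[ancestry]]; y <- p[[ancestry]]
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    stop("zero variance in parental ancestry proportions")
  }
  r_obs <- cor(x, y)
  groups <- if (within_groups && "population" %in% names(m)) {
    m$population
  } else {
    rep("all", n)
  }
  perm_r <- vapply(seq_len(n_perm), function(b) {
    yp <- y
    for (g in unique(groups)) {
      i <- which(groups == g)
      yp[i] <- y[sample(i, length(i))]
    }
    cor(x, yp)
  }, 1.0)
  list(r = r_obs, p_value = (1 + sum(perm_r >= r_obs)) / (n_perm + 1),
       n_pairs = n)
}

#' Summed pairwise IBD statistic
#'
#' Sums segment lengths at least `min_len_Mb` per individual pair, then
#' normalizes the group total by the number of eligible pairs:
#' `|A| * |B|` between two disjoint groups, or `choose(|A|, 2)` within a
#' single group (pass `groupB = NULL`).
#'
#' @param segments [read_ibd_segments()] tibble.
#' @param groupA,groupB Character vectors of individual ids; `groupB =
#'   NULL` for the within-group statistic.
#' @param min_len_Mb Minimum segment length (default 2 Mb).
#' @return List: `pair_sums` (tibble `id1`, `id2`, `total_Mb`),
#'   `statistic`.
#' @export
summed_pairwise_ibd <- function(segments, groupA, groupB = NULL,
                                min_len_Mb = 2) {
  if (!length(groupA)) stop("empty group")
  within <- is.null(groupB)
  if (!within) {
    if (!length(groupB)) stop("empty group")
    if (length(intersect(groupA, groupB))) {
      stop("groups must be disjoint for the between-group statistic")
    }
  }
  seg <- segments[segments$length_Mb >= min_len_Mb, ]
  eligible <- if (within) {
    seg$id1 %in% groupA & seg$id2 %in% groupA
  } else {
    (seg$id1 %in% groupA & seg$id2 %in% groupB) |
      (seg$id1 %in% groupB & seg$id2 %in% groupA)
  }
  seg <- seg[eligible, ]
  pair_sums <- seg |>
    dplyr::group_by(.data$id1, .data$id2) |>
    dplyr::summarise(total_Mb = sum(.data$length_Mb), .groups = "drop")
  denom <- if (within) choose(length(groupA), 2) else
    length(groupA) * length(groupB)
  list(pair_sums = pair_sums,
       statistic = sum(pair_sums$total_Mb) / denom)
}

#' Allele-frequency FST between two populations
#'
#' Nei-style ratio of sums: `FST = 1 - mean(H_S) / mean(H_T)` with
#' per-locus `H_S = (2 p1 q1 + 2 p2 q2) / 2` and `H_T = 2 p q` at the
#' mean frequency `p = (p1 + p2) / 2`. Symmetric in its arguments and
#' invariant to allele-label flips.
#'
#' @param p1,p2 Equal-length allele frequency vectors in \[0, 1\].
#' @return Scalar FST.
#' @export
frequency_fst <- function(p1, p2) {
  stopifnot(length(p1) == length(p2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (mean(ht) <= 0) {
    stop("FST undefined: all loci identically fixed in both populations")
  }
  1 - mean(hs) / mean(ht)
}

#' Convert calendar years to generations
#'
#' Uses a fixed generation time (30 years by default). `floor_to`
#' truncates the result to a grid (e.g. `0.1` counts completed tenths of
#' a generation), the convention under which 500 years is 16.6
#' generations; `NULL` returns the exact quotient.
#'
#' @param years Elapsed years.
#' @param generation_time Years per generation (default 30).
#' @param floor_to Optional truncation grid.
#' @return Generations.
#' @export
years_to_generations <- function(years, generation_time = 30,
                                 floor_to = NULL) {
  g <- years / generation_time
  if (!is.null(floor_to)) g <- floor(g / floor_to) * floor_to
  g
}

#' Convert generations to calendar years
#'
#' @param generations Number of generations.
#' @param generation_time Years per generation (default 30).
#' @return Years.
#' @export
generations_to_years <- function(generations, generation_time = 30) {
  generations * generation_time
}
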