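# admixkit

Tools for reconstructing the admixture history of recently admixed
populations — such as Caribbean and other Hispanic/Latino cohorts formed
by European, African and Native American contact over the last ~500
years — from phased SNP haplotypes.

Three connected analyses, plus the simulator that validates them:

* **Local ancestry inference.** Reference haplotypes are summarised by
  PCA in windows of 70 SNPs; per-population window scores are modelled
  as bivariate normals, and each admixed haplotype is decoded with a
  hidden Markov model whose transition between windows at distance *d*
  Morgans is `P(i→j) = exp(-g d) δij + (1 - exp(-g d)) qj`. Posterior
  calls at the 0.9 threshold feed ancestry masking; Viterbi paths feed
  tract-length analysis. A disjoint-HMM mode deconvolves
  sub-continental ancestry independently within each previously
  inferred continental block.
* **Tract-length demographic inference.** Maximal runs of constant
  ancestry are tallied into 50 equal length bins plus a
  whole-chromosome bin per ancestry (3 × 51 = 153 data points). A
  Markov model on the extended state space (ancestry, arrival
  generation) yields closed-form expected counts under
  founding-plus-pulses migration histories; bin counts are Poisson, and
  models are fitted by maximum likelihood and compared by
  `BIC = -2 log L + k log n` with `n = 153`.
* **Ancestry-specific PCA (ASPCA).** Admixed haplotypes are masked to
  one continental ancestry (everything else set missing) and fitted
  jointly with sub-continental reference panels by a regularized
  alternating-least-squares PCA on observed entries. Bivariate-normal
  cluster assignment — optionally stratified by a 50 cM tract-length
  cutoff — places haplotype fragments among candidate source
  populations, separating older (shorter-tract) from younger
  (longer-tract) contributions.
* **Cohort statistics.** X-vs-autosome ancestry bias (Wilcoxon signed
  rank), assortative-mating permutation tests (optionally within
  populations), summed pairwise IBD, and an allele-frequency FST.
* **Forward simulator.** Balding–Nichols founder populations,
  discrete-generation forward recombination (Rcpp), migrant pulses,
  ground-truth tract paintings, and parent-pair ancestry tables with
  tunable assortative-mating correlation and sex bias.

## A worked example

Simulate an admixed cohort with a known history, paint it, and fit the
demographic model back:

```r
library(admixkit)

# a 2-Morgan chromosome, two diverged source populations
map <- genetic_map(c("1", "1"), c(1, 20e6), c(0, 200))
variants <- uniform_variants(map, 1400)
base <- runif(1400, 0.1, 0.9)
fA <- draw_subpopulation_frequencies(base, 0.15, seed = 11)
fB <- draw_subpopulation_frequencies(base, 0.15, seed = 12)
anc <- ancestral_population_model(list(A = fA, B = fB), variants)
refs <- haplotype_panel(
  rbind(simulate_reference_haplotypes(fA, 30, variants, "A", seed = 21)$alleles,
        simulate_reference_haplotypes(fB, 30, variants, "B", seed = 22)$alleles),
  variants,
  tibble::tibble(sample_id = c(paste0("A", 1:15), paste0("B", 1:15)),
                 population = rep(c("A", "B"), each = 15)))

truth <- migration_model(6, c(A = 0.5, B = 0.5), N = 400)
cohort <- simulate_admixed_cohort(truth, anc, map, n_samples = 10, seed = 31)

wm <- fit_window_model(refs, window_size = 70)
painting <- infer_local_ancestry(cohort$panel, wm)
painting
#> <ancestry_painting> 20 haplotypes, g = 6.078, 131 tracts
```

The effective generations parameter lands near the simulated age of 6,
and the Viterbi tracts recover the truth at better than 90% of sites at
this divergence (`F = 0.15`). The tract histogram then drives the
demographic fit:

```r
hist <- bin_tract_lengths(painting$tracts, map, ancestries = c("A", "B"))
length(hist$counts)       # 2 ancestries x 51 bins
#> [1] 102
```

With three ancestries this count is 153, the `n` in the BIC. On
22-chromosome cohorts of 400 haplotypes, `fit_migration_model()`
recovers a founding time of 16 generations to within ±2 (see the
acceptance script), and `bic_select()` identifies which source sent a
second migrant pulse.

`autoplot()` methods display tract histograms and ASPCA scores;
`tidy()`/`glance()` return fitted parameters and model summaries as
tibbles.

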