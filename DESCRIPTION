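Package: admixkit
Title: Admixture Deconvolution: Local Ancestry, Ancestry-Specific PCA and
    Tract-Length Demographic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the admixture history of recently
    admixed populations from phased SNP data. Implements PCA-window hidden
    Markov model local ancestry inference, ancestry-specific principal
    component analysis (ASPCA) on masked haplotypes with missing data,
    tract-length based fitting of pulse-migration demographic models with
    BIC selection, size-stratified sub-continental source assignment, and
    cohort-level statistics (X-vs-autosome ancestry bias, assortative-mating
    permutation tests, summed pairwise IBD, allele-frequency FST). A
    forward admixture simulator with Balding-Nichols founder populations
    provides ground-truth ancestry paintings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
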