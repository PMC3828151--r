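# Shared fixture builders. Everything is generated in code at test time.

# two diverged reference populations plus matching allele-frequency model
# on a single chromosome of `total_cM` centiMorgans
make_two_pop_setup <- function(seed = 7, n_variants = 700, F_div = 0.15,
                               total_cM = 200, n_ref_haps = 30,
                               pops = c("A", "B")) {
  set.seed(seed)
  map <- genetic_map(c("1", "1"), c(1, 20e6), c(0, total_cM))
  variants <- uniform_variants(map, n_variants)
  base <- runif(n_variants, 0.1, 0.9)
  freqs <- lapply(seq_along(pops), function(i) {
    draw_subpopulation_frequencies(base, F_div,
                                   seed = child_seed(seed, pops[i]))
  })
  names(freqs) <- pops
  refs <- lapply(pops, function(p) {
    simulate_reference_haplotypes(freqs[[p]], n_ref_haps, variants,
                                  population = p,
                                  seed = child_seed(seed, paste0("ref", p)))
  })
  panel <- haplotype_panel(
    do.call(rbind, lapply(refs, function(r) r$alleles)),
    variants,
    dplyr::bind_rows(lapply(refs, function(r) r$labels))
  )
  list(map = map, variants = variants, base = base, freqs = freqs,
       refs = panel,
       anc_model = ancestral_population_model(freqs, variants))
}

# brute-force HMM posteriors / Viterbi by exhaustive path enumeration
enumerate_hmm <- function(loglik, g, q, distances) {
  W <- nrow(loglik); K <- ncol(loglik)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), W)))
  logw <- apply(paths, 1, function(pp) {
    lp <- log(q[pp[1]]) + loglik[1, pp[1]]
    if (W > 1) {
      for (w in 2:W) {
        P <- transition_matrix(g, distances[w - 1], q)
        lp <- lp + log(P[pp[w - 1], pp[w]]) + loglik[w, pp[w]]
      }
    }
    lp
  })
  wts <- exp(logw - max(logw))
  wts <- wts / sum(wts)
  post <- matrix(0, W, K)
  for (w in seq_len(W)) {
    for (k in seq_len(K)) post[w, k] <- sum(wts[paths[, w] == k])
  }
  list(posterior = post, viterbi = paths[which.max(logw), ],
       loglik = log(sum(exp(logw - max(logw)))) + max(logw))
}

# write a small phased VCF to a temp file and return the path
write_test_vcf <- function(gt, chrom, pos, samples,
                           ref = "A", alt = "G", path = tempfile(fileext = ".vcf")) {
  stopifnot(nrow(gt) == length(pos), ncol(gt) == length(samples))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], paste0("v", i), ref, alt, ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}
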