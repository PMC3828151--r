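# Tract-length demographic inference under pulse-migration models.
#
# The ancestry process along a chromosome is modelled as a Markov process
# on the extended state space (ancestry, arrival generation): a lineage
# that entered the population t generations ago accumulates crossovers at
# rate (t - 1) per Morgan, and a crossover incurred at meiosis u (counted
# from the present) re-draws the state from the ancestry pool of
# generation u + 1. Tract lengths of one ancestry are then phase-type
# distributed with end-censoring at chromosome boundaries, which produces
# a finite whole-chromosome mass.

# ---- extended-state generator ------------------------------------------

# Pools and generator for a discretized model.
# Returns: states (tibble: event, ancestry, time), Q (pool matrix,
# generations x states: Q[w, j] = P(random locus in generation-w pool is
# state j)), G (generator, per Morgan), pi (present-day pool = Q[1, ]).
tract_process_generator <- function(model) {
  d <- discretize_migration_model(model)
  anc <- d$ancestries
  nev <- length(d$time)
  # effective entry fraction per event: events at the same generation are
  # applied in listed order, later ones replacing part of earlier ones
  m_eff <- d$mag
  for (i in seq_len(nev)) {
    same <- which(d$time == d$time[i])
    after <- same[same > i]
    if (length(after)) m_eff[i] <- m_eff[i] * prod(1 - d$mag[after])
  }
  # states: (event, ancestry) with positive mass
  mass <- m_eff * d$src                       # nev x K entry fractions
  pos <- which(mass > 0, arr.ind = TRUE)
  states <- tibble::tibble(
    event = as.integer(pos[, 1]), ancestry = anc[pos[, 2]],
    time = d$time[pos[, 1]], entry = mass[pos]
  )
  states <- states[order(states$event, match(states$ancestry, anc)), ]
  ns <- nrow(states)
  Tmax <- max(d$time)
  # survival of a generation-t entrant down to generation w (w <= t):
  # product over events at generations in [w, t) of (1 - mag)
  surv <- function(t_from, w) {
    j <- which(d$time >= w & d$time < t_from)
    if (!length(j)) 1 else prod(1 - d$mag[j])
  }
  Q <- matrix(0, nrow = Tmax, ncol = ns)
  for (w in seq_len(Tmax)) {
    for (j in seq_len(ns)) {
      if (states$time[j] >= w) {
        Q[w, j] <- states$entry[j] * surv(states$time[j], w)
      }
    }
  }
  G <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    ti <- states$time[i]
    if (ti < 2) next
    for (j in seq_len(ns)) {
      if (j == i) next
      wmax <- min(ti, states$time[j])
      if (wmax >= 2) G[i, j] <- sum(Q[2:wmax, j])
    }
    G[i, i] <- -sum(G[i, -i])
  }
  list(states = states, Q = Q, G = G, pi = Q[1, ], ancestries = anc)
}

# eigen-based matrix-function helper for a sub-generator: returns a
# function(kind, a, b) giving E(b)=e^{Gb} ("exp"), I0 = int_a^b e^{Gl} dl,
# or I1 = int_a^b l e^{Gl} dl, as real matrices.
subgen_calculus <- function(G) {
  n <- nrow(G)
  if (n == 0) return(NULL)
  eg <- eigen(G)
  V <- eg$vectors
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  lam <- eg$values
  use_eigen <- !is.null(Vi) &&
    max(abs(Re(V %*% (lam * Vi)) - G)) < 1e-8 * max(1, max(abs(G)))
  f_exp <- function(l, x) exp(l * x)
  f_i0 <- function(l, a, b) {
    out <- (exp(l * b) - exp(l * a)) / l
    z <- abs(l) < 1e-10
    if (any(z)) out[z] <- b - a
    out
  }
  f_i1 <- function(l, a, b) {
    out <- (b * exp(l * b) - a * exp(l * a)) / l -
      (exp(l * b) - exp(l * a)) / l^2
    z <- abs(l) < 1e-10
    if (any(z)) out[z] <- (b^2 - a^2) / 2
    out
  }
  apply_f <- function(vals) Re(V %*% (vals * Vi))
  if (use_eigen) {
    list(
      expm = function(x) apply_f(f_exp(lam, x)),
      i0 = function(a, b) apply_f(f_i0(lam, a, b)),
      i1 = function(a, b) apply_f(f_i1(lam, a, b))
    )
  } else {
    # quadrature fallback (defective generator): Simpson on 32 panels
    list(
      expm = function(x) as.matrix(Matrix::expm(G * x)),
      i0 = function(a, b) simpson_mat(function(l) {
        as.matrix(Matrix::expm(G * l))
      }, a, b),
      i1 = function(a, b) simpson_mat(function(l) {
        l * as.matrix(Matrix::expm(G * l))
      }, a, b)
    )
  }
}

simpson_mat <- function(f, a, b, n = 32) {
  xs <- seq(a, b, length.out = 2 * n + 1)
  h <- (b - a) / (2 * n)
  wts <- c(1, rep(c(4, 2), n - 1), 4, 1)
  out <- 0
  for (i in seq_along(xs)) out <- out + wts[i] * f(xs[i])
  out * h / 3
}

#' Histogram observed tract lengths
#'
#' Tallies tracts by ancestry into `n_bins` equal-width length bins on
#' `[0, L_max]` Morgans (`L_max` = longest chromosome) plus one extra bin
#' for whole-chromosome tracts. Tracts flagged whole-chromosome go to the
#' extra bin regardless of length; all other tracts are binned by
#' `floor(length / width)` with the last regular bin right-closed.
#'
#' @param tracts A [tract_set()] tibble (lengths in cM).
#' @param chrom_lengths Named vector of chromosome lengths in Morgans, or
#'   a [genetic_map()] from which they are computed.
#' @param n_bins Number of regular bins (default 50).
#' @param ancestries Ancestries to tally; defaults to those present,
#'   sorted.
#' @return Object of class `tract_histogram` with `counts`
#'   (ancestry x bins matrix, `n_bins + 1` columns), `bin_edges`,
#'   `chrom_lengths`, `n_haplotypes`.
#' @export
bin_tract_lengths <- function(tracts, chrom_lengths, n_bins = 50,
                              ancestries = NULL) {
  if (is.data.frame(chrom_lengths)) {
    cl <- chrom_lengths_morgans(chrom_lengths)
    chrom_lengths <- setNames(cl$length_M, cl$chrom)
  }
  L_max <- max(chrom_lengths)
  if (is.null(ancestries)) ancestries <- sort(unique(tracts$ancestry))
  width <- L_max / n_bins
  len_M <- tracts$length_cM / 100
  if (any(len_M > L_max * (1 + 1e-9) & !tracts$is_whole_chromosome)) {
    stop("tract longer than the longest chromosome but not flagged whole")
  }
  counts <- matrix(0L, nrow = length(ancestries), ncol = n_bins + 1,
                   dimnames = list(ancestries, NULL))
  for (a in ancestries) {
    sel <- tracts$ancestry == a
    whole <- sel & tracts$is_whole_chromosome
    reg <- sel & !tracts$is_whole_chromosome
    b <- pmin(floor(len_M[reg] / width), n_bins - 1) + 1
    tb <- tabulate(b, nbins = n_bins)
    counts[a, ] <- c(tb, sum(whole))
  }
  structure(
    list(counts = counts, bin_edges = seq(0, L_max, length.out = n_bins + 1),
         chrom_lengths = chrom_lengths,
         n_haplotypes = length(unique(tracts$hap_id)),
         ancestries = ancestries),
    class = "tract_histogram"
  )
}

#' @exportS3Method base::print
print.tract_histogram <- function(x, ...) {
  cat("<tract_histogram> ", nrow(x$counts), " ancestries x ",
      ncol(x$counts), " bins (last = whole-chromosome), ",
      sum(x$counts), " tracts from ", x$n_haplotypes, " haplotypes\n",
      sep = "")
  invisible(x)
}

#' Expected tract-length histogram under a pulse-migration model
#'
#' Computes, for each ancestry and length bin, the expected number of
#' tracts per cohort from the extended-state Markov painting model:
#' interior tracts, tracts censored at one chromosome end, and
#' whole-chromosome tracts (extra bin) are accounted separately via
#' phase-type closed forms, then summed over chromosomes and scaled by
#' `n_haplotypes`.
#'
#' @param model A [migration_model()].
#' @param chrom_lengths Named vector of chromosome lengths (Morgans) or a
#'   [genetic_map()].
#' @param n_haplotypes Number of haplotypes in the cohort.
#' @param n_bins Number of regular bins (default 50).
#' @param L_max Bin range maximum; defaults to the longest chromosome.
#' @param ancestries Ancestry order of the output; defaults to the model's.
#' @return A `tract_histogram` whose `counts` are expected (real) counts.
#' @export
expected_histogram <- function(model, chrom_lengths, n_haplotypes,
                               n_bins = 50, L_max = NULL,
                               ancestries = NULL) {
  if (is.data.frame(chrom_lengths)) {
    cl <- chrom_lengths_morgans(chrom_lengths)
    chrom_lengths <- setNames(cl$length_M, cl$chrom)
  }
  if (is.null(L_max)) L_max <- max(chrom_lengths)
  gen <- tract_process_generator(model)
  if (is.null(ancestries)) ancestries <- gen$ancestries
  edges <- seq(0, L_max, length.out = n_bins + 1)
  counts <- matrix(0, nrow = length(ancestries), ncol = n_bins + 1,
                   dimnames = list(ancestries, NULL))
  for (a in ancestries) {
    sk <- which(gen$states$ancestry == a)
    if (!length(sk)) next
    Gss <- gen$G[sk, sk, drop = FALSE]
    r <- -rowSums(Gss)
    pik <- gen$pi[sk]
    beta <- colSums(gen$G[-sk, sk, drop = FALSE] *
                      gen$pi[-sk]) # entering rate per Morgan
    if (length(sk) == nrow(gen$states)) beta <- rep(0, length(sk))
    calc <- subgen_calculus(Gss)
    ones <- rep(1, length(sk))
    # per-bin scalars over the full bin [a0, b0]; the chromosome length
    # C enters the interior term only linearly, so per chromosome the
    # regular-bin counts are C * s0 - s1 + sL + sR for bins below C
    s0 <- s1 <- sL <- sR <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      I0 <- calc$i0(edges[b], edges[b + 1])
      I1 <- calc$i1(edges[b], edges[b + 1])
      s0[b] <- drop(beta %*% I0 %*% r)
      s1[b] <- drop(beta %*% I1 %*% r)
      sL[b] <- drop(pik %*% I0 %*% r)
      sR[b] <- drop(beta %*% I0 %*% ones)
    }
    bin_terms <- function(a0, b0, C) {
      I0 <- calc$i0(a0, b0)
      I1 <- calc$i1(a0, b0)
      drop(beta %*% (C * I0 - I1) %*% r) + drop(pik %*% I0 %*% r) +
        drop(beta %*% I0 %*% ones)
    }
    for (ci in seq_along(chrom_lengths)) {
      C <- chrom_lengths[ci]
      # bins fully below C, then at most one bin straddling C
      n_full <- sum(edges[-1] <= C)
      if (n_full > 0) {
        full <- seq_len(n_full)
        counts[a, full] <- counts[a, full] +
          C * s0[full] - s1[full] + sL[full] + sR[full]
      }
      if (n_full < n_bins && edges[n_full + 1] < C) {
        b <- n_full + 1
        counts[a, b] <- counts[a, b] + bin_terms(edges[b], C, C)
      }
      counts[a, n_bins + 1] <- counts[a, n_bins + 1] +
        drop(pik %*% calc$expm(C) %*% ones)
    }
  }
  counts <- counts * n_haplotypes
  structure(
    list(counts = counts, bin_edges = edges, chrom_lengths = chrom_lengths,
         n_haplotypes = n_haplotypes, ancestries = ancestries),
    class = "tract_histogram"
  )
}

#' Monte Carlo simulation of the Markov tract painting
#'
#' Independent simulation oracle for [expected_histogram()]: simulates the
#' extended-state jump process directly from its definition. A painting
#' starts in a state drawn from the present-day pool; a state of age t
#' accumulates crossovers at rate (t - 1) per Morgan, each crossover picks
#' a meiosis u uniformly from 1..(t - 1) and re-draws the state from the
#' generation-(u + 1) pool.
#'
#' @param model A [migration_model()].
#' @param C Chromosome length in Morgans.
#' @param n_paintings Number of independent chromosomes to paint.
#' @param seed Optional seed.
#' @return Tibble with columns `painting`, `ancestry`, `length_M`,
#'   `is_whole_chromosome`.
#' @export
simulate_tract_painting_mc <- function(model, C, n_paintings,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gen <- tract_process_generator(model)
  states <- gen$states
  ns <- nrow(states)
  tvec <- states$time
  avec <- states$ancestry
  Qcum <- t(apply(gen$Q, 1, cumsum))
  if (ns == 1) Qcum <- matrix(Qcum, ncol = 1)

  n <- n_paintings
  s <- sample.int(ns, n, replace = TRUE, prob = gen$pi)
  pos <- numeric(n)
  tract_start <- numeric(n)
  whole <- rep(TRUE, n)
  active <- rep(TRUE, n)
  acc_p <- list(); acc_a <- list(); acc_l <- list(); acc_w <- list()
  push <- function(p, a, l, w) {
    k <- length(acc_p) + 1
    acc_p[[k]] <<- p; acc_a[[k]] <<- a; acc_l[[k]] <<- l; acc_w[[k]] <<- w
  }
  # all paintings advance one crossover per sweep (vectorized)
  while (any(active)) {
    i <- which(active)
    step <- stats::rexp(length(i), tvec[s[i]] - 1)
    newpos <- pos[i] + step
    done <- newpos >= C
    if (any(done)) {
      di <- i[done]
      push(di, avec[s[di]], C - tract_start[di], whole[di])
      active[di] <- FALSE
    }
    ri <- i[!done]
    if (!length(ri)) next
    pos[ri] <- newpos[!done]
    u <- floor(runif(length(ri)) * (tvec[s[ri]] - 1)) + 1
    r <- runif(length(ri))
    news <- rowSums(Qcum[u + 1, , drop = FALSE] < r) + 1L
    changed <- avec[news] != avec[s[ri]]
    if (any(changed)) {
      ci <- ri[changed]
      push(ci, avec[s[ci]], pos[ci] - tract_start[ci],
           rep(FALSE, length(ci)))
      whole[ci] <- FALSE
      tract_start[ci] <- pos[ci]
    }
    s[ri] <- news
  }
  out <- tibble::tibble(
    painting = unlist(acc_p), ancestry = unlist(acc_a),
    length_M = unlist(acc_l), is_whole_chromosome = unlist(acc_w)
  )
  dplyr::arrange(out, .data$painting)
}

#' Poisson log-likelihood of an observed histogram
#'
#' `LL = sum(o * log(e) - e - log(o!))` over all bins, with expected
#' counts floored at 1e-9.
#'
#' @param observed,expected `tract_histogram` objects or bare count
#'   matrices/vectors of matching shape.
#' @return Scalar log-likelihood.
#' @export
poisson_loglikelihood <- function(observed, expected) {
  o <- if (inherits(observed, "tract_histogram")) observed$counts else observed
  e <- if (inherits(expected, "tract_histogram")) expected$counts else expected
  stopifnot(length(o) == length(e))
  if (any(o < 0)) stop("negative observed counts")
  e <- pmax(e, 1e-9)
  sum(o * log(e) - e - lgamma(o + 1))
}

# parse a structure tag like "EUR,NAT+AFR" or "EUR,NAT+AFR+EUR"
parse_structure <- function(structure) {
  parts <- strsplit(structure, "+", fixed = TRUE)[[1]]
  founding <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  if (length(founding) != 2 || length(parts) < 2 || length(parts) > 3) {
    stop("structure tag must look like 'A,B+C' or 'A,B+C+D'")
  }
  list(founding = founding, pulse1 = parts[2],
       pulse2 = if (length(parts) == 3) parts[3] else NULL)
}

build_structure_model <- function(struct_def, T1, p, T2, m2, T3 = NULL,
                                  m3 = NULL, N = 5000) {
  founding <- setNames(c(p, 1 - p), struct_def$founding)
  pulses <- tibble::tibble(time = T2, source = struct_def$pulse1, magnitude = m2)
  if (!is.null(struct_def$pulse2)) {
    pulses <- dplyr::bind_rows(
      pulses,
      tibble::tibble(time = T3, source = struct_def$pulse2, magnitude = m3)
    )
  }
  migration_model(T1, founding, pulses, N = N)
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Fit a pulse-migration model to a tract histogram
#'
#' Maximizes the Poisson likelihood of the observed histogram over the
#' model parameters by Nelder-Mead on transformed coordinates (times via
#' log/logistic, proportions and magnitudes via logit), from `n_restarts`
#' random starting points; the best likelihood is kept. Times are
#' continuous during optimization and reported both raw and rounded to
#' integer generations.
#'
#' @param hist A [bin_tract_lengths()] histogram. Ancestry names must
#'   match the structure tag.
#' @param structure Structure tag: `"A,B+C"` (founding by A and B at T1,
#'   later pulse of C at T2; 4 free parameters) or `"A,B+C+D"` (extra
#'   pulse of D at T3; 6 parameters).
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Seed for the restarts.
#' @param T1_range Founding-time search range in generations.
#' @return Object of class `tracts_fit` with the fitted
#'   [migration_model()], log-likelihood, parameter count `k`, data-point
#'   count `n`, and BIC.
#' @export
fit_migration_model <- function(hist, structure, n_restarts = 10,
                                seed = 1, T1_range = c(4, 40)) {
  struct_def <- parse_structure(structure)
  two_pulse <- !is.null(struct_def$pulse2)
  obs <- hist$counts
  n_bins <- ncol(obs) - 1
  L_max <- max(hist$bin_edges)
  anc_needed <- unique(c(struct_def$founding, struct_def$pulse1, struct_def$pulse2))
  missing_anc <- setdiff(anc_needed, rownames(obs))
  if (length(missing_anc)) {
    stop("histogram lacks ancestry: ", paste(missing_anc, collapse = ", "))
  }

  theta_to_model <- function(th) {
    T1 <- 2 + exp(th[1])
    p <- logistic(th[2])
    T2 <- 1 + (T1 - 1) * logistic(th[3])
    m2 <- logistic(th[4])
    T3 <- if (two_pulse) 1 + (T1 - 1) * logistic(th[5]) else NULL
    m3 <- if (two_pulse) logistic(th[6]) else NULL
    build_structure_model(struct_def, T1, p, T2, m2, T3, m3)
  }
  negll <- function(th) {
    m <- tryCatch(theta_to_model(th), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    eh <- tryCatch(
      expected_histogram(m, hist$chrom_lengths, hist$n_haplotypes,
                         n_bins = n_bins, L_max = L_max,
                         ancestries = rownames(obs)),
      error = function(e) NULL
    )
    if (is.null(eh) || any(!is.finite(eh$counts))) return(1e10)
    -poisson_loglikelihood(obs, pmax(eh$counts, 0))
  }

  set.seed(seed)
  npar <- if (two_pulse) 6 else 4
  best <- NULL
  n_fail <- 0
  for (r in seq_len(n_restarts)) {
    th0 <- c(log(runif(1, T1_range[1], T1_range[2]) - 2),
             logit(runif(1, 0.15, 0.85)),
             logit(runif(1, 0.15, 0.85)),
             logit(runif(1, 0.05, 0.5)))
    if (two_pulse) th0 <- c(th0, logit(runif(1, 0.1, 0.6)),
                            logit(runif(1, 0.05, 0.5)))
    fit <- tryCatch(
      optim(th0, negll, method = "Nelder-Mead",
            control = list(maxit = 800, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
      n_fail <- n_fail + 1
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all ", n_restarts, " restarts failed")
  model <- theta_to_model(best$par)
  ll <- -best$value
  n <- length(obs)
  k <- npar
  th <- best$par
  T1_hat <- 2 + exp(th[1])
  params <- tibble::tibble(
    parameter = c("T1", paste0("p_", struct_def$founding[1]),
                  "T2", paste0("m_", struct_def$pulse1),
                  if (two_pulse) c("T3", paste0("m_", struct_def$pulse2))),
    value = c(T1_hat, logistic(th[2]),
              1 + (T1_hat - 1) * logistic(th[3]), logistic(th[4]),
              if (two_pulse) c(1 + (T1_hat - 1) * logistic(th[5]),
                               logistic(th[6])))
  )
  structure(
    list(structure = structure, model = model, params = params,
         loglik = ll, k = k, n = n, bic = -2 * ll + k * log(n),
         converged = best$convergence == 0, n_restarts = n_restarts,
         n_failed = n_fail),
    class = "tracts_fit"
  )
}

#' @exportS3Method base::print
print.tracts_fit <- function(x, ...) {
  cat("<tracts_fit> ", x$structure, ": logLik = ",
      format(x$loglik, digits = 6), ", k = ", x$k, ", BIC = ",
      format(x$bic, digits = 6), "\n", sep = "")
  cat("  T1 = ", format(x$model$T1, digits = 3), " generations (rounded: ",
      round(x$model$T1), ")\n", sep = "")
  invisible(x)
}

#' Select the best model by BIC
#'
#' `BIC = -2 logL + k log(n)`; the minimum wins, ties go to the model with
#' fewer parameters.
#'
#' @param fits List of [fit_migration_model()] results (>= 2).
#' @param n Data-point count; defaults to each fit's own `n` (3 ancestries
#'   x 51 bins = 153 under the default binning).
#' @return The winning `tracts_fit`, with attribute `"bic_table"`.
#' @export
bic_select <- function(fits, n = NULL) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  tb <- purrr::map_dfr(fits, function(f) {
    nn <- if (is.null(n)) f$n else n
    tibble::tibble(structure = f$structure, loglik = f$loglik, k = f$k,
                   n = nn, bic = -2 * f$loglik + f$k * log(nn))
  })
  ord <- order(tb$bic, tb$k)
  best <- fits[[ord[1]]]
  attr(best, "bic_table") <- tb
  best
}

#' Present-day ancestry proportions implied by a fit
#'
#' @param fit A [fit_migration_model()] result.
#' @return Named proportion vector from [ancestry_trajectory()].
#' @export
model_final_proportions <- function(fit) {
  present_proportions(fit$model)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a migration-model fit
#'
#' @param x A `tracts_fit`.
#' @param ... Unused.
#' @return Tibble of fitted parameters (times in generations, proportions
#'   and pulse magnitudes as fractions).
#' @export
tidy.tracts_fit <- function(x, ...) {
  x$params
}

#' One-row model summary of a migration-model fit
#'
#' @param x A `tracts_fit`.
#' @param ... Unused.
#' @export
glance.tracts_fit <- function(x, ...) {
  tibble::tibble(structure = x$structure, logLik = x$loglik, k = x$k,
                 n = x$n, BIC = x$bic, converged = x$converged,
                 T1_generations = round(x$model$T1))
}
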