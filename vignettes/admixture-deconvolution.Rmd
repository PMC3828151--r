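---
title: "Models and methods for admixture deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for admixture deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

admixkit reconstructs the admixture history of recently admixed
populations from phased SNP haplotypes. This vignette is the package's
account of the models it implements, the assumptions they make, the
tunable parameters that matter, and the choices made where the design
was genuinely open. Nothing here reports an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The pipeline at a glance

Three analyses share one data model:

1. **Local ancestry inference** assigns each window of each phased
   haplotype to one of K continental ancestries, using PCA of reference
   panels in windows of 70 SNPs and a hidden Markov model along the
   chromosome.
2. **Tract-length demographic inference** summarises the maximal runs of
   constant ancestry ("tracts") into a 51-bin length histogram per
   ancestry and fits pulse-migration models by Poisson likelihood, with
   BIC to choose among model structures.
3. **Ancestry-specific PCA (ASPCA)** masks each admixed haplotype down
   to one continental ancestry and runs a missing-data PCA jointly with
   sub-continental reference panels, to place the surviving haplotype
   fragments among candidate source populations — optionally stratified
   by tract length, which separates older (shorter) from younger
   (longer) contributions.

A forward admixture simulator generates cohorts with known ancestry
paintings; every statistical claim the package makes is validated
against it or against exhaustive/closed-form oracles.

## Local ancestry: PCA windows and the transition model

Reference haplotypes are pooled and, per window of `window_size = 70`
SNPs, projected onto the first two principal components; each reference
population's window scores are summarised by a bivariate normal. A
window in which all reference haplotypes are identical carries no
information and is flagged; it contributes equal log-likelihoods to all
ancestries. The 70-SNP default reflects array-density data, where that
window length corresponds to roughly 10,000 windows genome-wide; for
the simulated fixtures in the tests the same window size is kept and
the genome is scaled instead.

Between adjacent windows at genetic distance $d$ Morgans the HMM uses

$$P(i \to j) = e^{-gd}\,\delta_{ij} + (1 - e^{-gd})\,q_j,$$

where $q$ is the vector of expected ancestry proportions (also the
stationary distribution of this kernel) and $g$ is an *effective*
generations-since-admixture parameter. $g$ is optimized per population
by golden-section search on $\log g$ over $[1, 500]$, maximizing the
summed forward log-likelihood; it correlates with, but is not an
estimator of, the true admixture time — simulation recovery is only
tested to within a factor of two. Inter-window distance is measured
between window midpoint variants (the convention is not forced by the
model; midpoints behave sensibly when windows have unequal spans).

Posterior decoding (forward–backward) supplies per-window posterior
probabilities; calls at the 0.9 posterior threshold (with `"unknown"`
below it) feed ASPCA masking, while Viterbi paths — which never contain
`"unknown"` — feed tract-length analysis. This split matters: masking
wants conservative, high-precision calls, while tract lengths want a
single consistent path whose run lengths are interpretable. Viterbi
ties are broken toward the lowest ancestry index, deterministically.
Tract boundaries are placed at the midpoint between the last variant of
one window and the first of the next, in both cM and bp. A chromosome
whose windows all share one label becomes a single tract flagged
whole-chromosome.

Remainder SNPs at a chromosome end (fewer than `window_size`) are
merged into the final full window rather than forming an unstable tiny
window.

For sub-continental deconvolution *within* previously inferred
continental blocks, a separate window model and HMM are fitted per
block, on the block's variant span only ("disjoint HMMs"); no
information flows across block boundaries, so a junction between two
blocks cannot manufacture a spurious switch. Blocks shorter than one
window are skipped with a warning. Within-block analyses default to a
smaller effective `g` than genome-wide painting because a block, by
construction, rarely contains more than a handful of sub-ancestry
switches.

## Tract lengths: the extended-state Markov painting model

Time is counted in generations before present: the founding event is
`T1` generations ago, the sampled individuals are generation 1, and a
founder lineage has therefore passed through `T1 - 1` meioses. A pulse
at time $t$ with magnitude $m$ replaces a fraction $m$ of the
population with unadmixed source chromosomes.

Along a chromosome, the ancestry process is modelled as Markov on the
extended state space (ancestry, arrival generation): a lineage that
arrived $t$ generations ago accumulates crossovers at rate $t - 1$ per
Morgan; a crossover incurred at meiosis $u$ re-draws the state from the
ancestry pool of generation $u + 1$, i.e. from all migration events at
least that old, weighted by their entry fractions and survival through
later replacement events. Tract lengths of one ancestry are then
phase-type distributed. Expected bin counts decompose into interior
tracts, tracts censored at one chromosome end, and whole-chromosome
tracts (the extra 51st bin); all three terms have closed forms in the
sub-generator $G_{ss}$ of the ancestry's states, evaluated by
eigendecomposition (with a Padé matrix exponential plus Simpson
quadrature fallback should the eigenbasis be ill-conditioned). Because
the chromosome length enters the interior term linearly, per-bin
integrals are computed once and reused across all 22 chromosomes.

The observed histogram uses 50 equal-width bins on $[0, L_{max}]$
(longest chromosome) plus the whole-chromosome bin; with three
ancestries this gives the 153 data points that enter
$\mathrm{BIC} = -2\log L + k\log n$, $n = 153$. Bin counts are treated
as independent Poisson; expected counts are floored at $10^{-9}$ so
empty bins cannot produce infinite log-likelihoods.

Fitting maximizes the Poisson likelihood by Nelder–Mead on transformed
coordinates: $\log(T_1 - 2)$, logit of the founding proportion, pulse
times as logits of their position within $(1, T_1)$, and logits of
magnitudes. Times are continuous during optimization; a pulse at a
fractional time $n + f$ is split across the flanking integer
generations with magnitudes chosen to preserve the total replaced
fraction, and a fractional founding time interpolates between full
foundings at $n$ and $n+1$. This smoothing makes the likelihood
continuous in time parameters. Reported times are rounded to integer
generations. The free-parameter counts are k = 4 for the
founding-plus-one-pulse structure and k = 6 with an extra pulse; ties
in BIC go to the smaller model.

One- versus two-pulse histories are distinguishable by shape: a single
pulse gives exponential decay of tract abundance with length (log-scale
straight line), while a second pulse of the same ancestry adds an
excess of long tracts, bending the log-scale curve away from the line
(a mixture of two exponential decays; the fitted quadratic term turns
positive). The tests assert this signature both on the analytic
expectations and on forward-simulated cohorts.

## The forward simulator

The simulator is a discrete-generation forward model, not a coalescent:
the tract model above assumes Markov paintings, and a forward
population reproduces exactly the ingredients that assumption
idealises. At founding, $2N$ haplotypes are labelled by the founding
proportions. Each later generation, every haplotype is a recombinant of
two randomly chosen previous-generation haplotypes with a Poisson
(length in Morgans) number of crossovers placed uniformly in genetic
distance — no interference, matching the model. Pulses replace whole
individuals (two unadmixed haplotypes each). Alleles are painted onto
the sampled haplotypes from per-ancestry site frequencies, so reference
and admixed panels share a common frequency model; sub-continental
panels are derived from a base frequency vector by Balding–Nichols
draws, $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, with divergence $F$.

The default population size is $N = 5000$ diploids, balancing drift
against runtime. Finite $N$ matters: drift and shared pedigree
correlate the sampled haplotypes and overdisperse bin counts relative
to Poisson, which is visible as a small upward curvature even in
single-pulse log-scale histograms and as a likelihood bonus that a
nested extra-pulse model can soak up. For this reason the structure
selection study generates data under a genuine two-pulse model (second
magnitude 0.15) and asks BIC to recover it, while the founding-time
recovery study fits the generating simple structure. The replicate
studies in the tests and acceptance script use $N = 1000$, 400
haplotypes, and 22 chromosomes of human-like genetic lengths (2.8 down
to 0.5 Morgans); these sizes are the package's documented study
conditions.

What the simulator does *not* emulate: linkage disequilibrium within
ancestral populations (sites are independent given ancestry), crossover
interference, sex-specific recombination, genotyping error, and phasing
switch errors. Passing tests therefore demonstrate correctness of the
algorithms under the model's own assumptions, not robustness to every
artefact of real array data. X-chromosome proportions in the
parent-pair generator are produced directly by shifting autosomal
proportions toward a designated ancestry and re-normalizing — they are
not transmitted through a pedigree.

Parent pairs use a Gaussian copula: the correlated ancestry component
has Beta marginals linked by a bivariate normal with correlation set to
the target; monotone transforms attenuate the Pearson correlation only
mildly, which the generator's tests bound empirically. Reproducibility
uses one master seed with deterministically derived child seeds (a
small polynomial hash; distinct components give distinct seeds).

## ASPCA: PCA with ancestry-masked data

Masking keeps alleles only at variants inside windows called the target
ancestry at posterior ≥ 0.9; everything else becomes missing, and
haplotypes below a genome-wide target fraction threshold (3% was used
for Native American analyses, 25% for European and African ones) are
excluded. Reference rows are fully observed.

The fit minimizes

$$\sum_{(r,c)\ \mathrm{observed}} (x_{rc} - \mu_c - \textstyle\sum_k
u_{rk} w_{ck})^2 + \lambda(\|U\|^2 + \|W\|^2)$$

by alternating exact row/column least squares, with observed-entry
column means $\mu_c$, ridge penalty
$\lambda = 10^{-3}\,(\#\mathrm{observed})/(\#\mathrm{rows})$ by
default, and random initialisation under a caller-supplied seed.
Columns observed in fewer than two rows are dropped, as are rows with
fewer than `min_observed` sites (default 500, sized for genome-scale
input — lower it for small fixtures). Convergence requires both the
relative objective change and the relative change of the fitted
low-rank surface to fall below `tol`: the objective flattens well
before the subspace settles, and stopping on the objective alone leaves
scores short of their final values. After convergence the factors are
orthonormalized (loadings orthonormal, scores carrying the variance,
ordered by singular value) and sign-fixed so each component's
largest-magnitude loading is positive. With no missing data and
$\lambda = 0$ this reproduces classical PCA scores up to sign.

Exact update equations from the original subspace-PCA derivation are
not available here; regularized alternating least squares is the
member of that algorithm family implemented, and the package's tests
pin down its behaviour (PCA equivalence, rank-1 recovery through 30%
missingness, monotone objective) rather than any specific iteration
schedule.

Projection of a partially observed haplotype onto fixed reference
loadings solves the least-squares problem restricted to the observed
sites, with a $10^{-10}$ ridge for numerical safety.

## Source assignment and the length-stratified analysis

Per reference population a bivariate normal is fitted to its score
cluster (maximum-likelihood covariance plus $\varepsilon I$ shrinkage,
$\varepsilon = 10^{-4} \times$ mean diagonal, floored at $10^{-8}$);
populations with fewer than three reference rows are dropped.
Assignment probabilities are normalized densities computed in log
space, so distant points underflow gracefully rather than erroring.
Cohort summaries report the mean probability per population with its
standard error of the mean, and the means rescaled to sum to one.

Tract-length classes split at 50 cM (`short` < 50 ≤ `long`; the
boundary value closes the upper class, since strictly-less/
strictly-greater definitions would leave exactly-50 unassigned), with a
(5, 50) cM `medium` class available to show the short-class signal is
not an artefact of the very shortest, most misassignment-prone tracts.
The size-stratified analysis is per haplotype: the reference PCA is
recomputed on exactly the sites that haplotype retains in the class,
the cluster Gaussians refitted, and the haplotype projected — so
reference and test points always live in the same, class-specific
space.

The qualitative expectation this machinery reproduces on synthetic
data: when one source contributed at the founding (old, short tracts)
and another in a recent pulse (young, long tracts), short-class
assignments favour the older source, long-class assignments the
younger, and the older-source fraction of confidently called windows
declines monotonically with block size.

## Statistical tests

* **X-vs-autosome bias**: Wilcoxon signed-rank on paired per-female
  differences of one ancestry's X and autosomal proportions; zero
  differences are dropped (the classical convention; the dropped count
  is reported), exact null for n ≤ 25 without ties. The test is
  two-sided and deliberately silent on direction; the median difference
  is reported alongside.
* **Assortative mating**: Pearson correlation of maternal and paternal
  proportions against a null of re-paired fathers, globally or within
  population labels (to separate mate choice from population
  structure); one-sided p with the +1 finite-sample correction, so a
  permutation p-value is never zero.
* **Centroid deviation**: Fisher's method combines two-sample t-tests
  on the first two score axes (admixed vs pooled reference); the null
  resamples the two reference subgroups and compares them to each
  other. Because that null embeds the subgroups' frozen mean difference
  as a model of intrinsic reference structure, the test is
  *conservative* under a pure sampling null — its p-values are
  super-uniform (measured type-I error of 1–2% at nominal 5%). This is
  a property of the test's design, not a defect: it asks whether the
  admixed deviation exceeds differences already present within the
  reference cluster. The admixed group is not resampled, following the
  method's published description.
* **Summed pairwise IBD**: per-pair sums of segments ≥ 2 Mb, normalized
  by |A|·|B| between groups or C(|A|,2) within one.
* **FST**: Nei-style ratio of locus-averaged heterozygosities,
  $1 - \bar H_S / \bar H_T$. The clustering software whose statistic
  this mirrors does not print its internal formula; this estimator is
  documented as an approximation and isolated behind one function.

Generation/year conversion uses 30 years per generation; the
`floor_to` argument counts completed grid units (e.g. tenths of a
generation), the convention under which 500 years is 16.6 generations
rather than 16.7.

## Numerical choices and degenerate inputs

* Window covariances and cluster Gaussians are shrunk by
  $\varepsilon I$ to guarantee positive definiteness with tens of
  reference haplotypes.
* Forward–backward and Viterbi run in scaled arithmetic / log space; a
  window whose likelihoods are all $-\infty$ is an error, not a silent
  NaN.
* The phase-type engine falls back from eigendecomposition to
  Padé-plus-Simpson when the eigenbasis reconstruction error exceeds
  $10^{-8}$.
* Permutation and bootstrap p-values always use the +1 correction.
* BED output is 0-based half-open; all internal bp coordinates are
  1-based inclusive. Multi-allelic VCF records are skipped with a
  warning (array data are biallelic); unphased or missing genotypes are
  hard errors because the panel contract is completeness.

## Known limitations

Diploid joint decoding, phasing-error correction, coalescent
simulation, crossover interference, continuous-migration demographic
models, and confidence intervals on fitted times (point estimates plus
BIC only) are out of scope. The g parameter is effective, not literal.
ASPCA axes are reported unrotated; display rotations used in published
maps are presentation choices, not part of the method.
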