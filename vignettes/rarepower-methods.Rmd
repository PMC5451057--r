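---
title: "Methods: simulating and comparing rare-variant association tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing rare-variant association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package answers

Gene-based tests of rare single-nucleotide variants (SNVs) come in two
families.  A *single-marker test* (SMT) regresses the trait on one variant
at a time and declares a gene significant when any of its variants survives
a multiplicity correction (the minP rule).  *Multi-marker tests* (MMTs)
pool the variants of a gene into one statistic: a burden test collapses
them into a single allele count, while SKAT and SKAT-O form weighted
variance-component score statistics.  For quantitative traits the relative
power of the two families has to be compared on the *same* hypothesis —
identifying the same causal gene — which is the comparison this package
implements as a reproducible Monte-Carlo pipeline: genotype simulation,
phenotype generation under a scenario grid, all four tests, and power /
type-I-error estimation with quantified Monte-Carlo error.

# Genotype engine

Genotypes come from a neutral coalescent with recombination (the msprime
simulator, driven through a helper script shipped with the package): a pool
of 10,000 haplotypes over a 200 kb region, from which each Monte-Carlo
replicate samples a uniformly random 3 kb "gene" window (half-open
`[s, s + L)` coordinates) and pairs 2,000 haplotypes drawn without
replacement into n = 1,000 diploid genotype rows coded 0/1/2 by minor
allele count.  Monomorphic columns are dropped; orientation to the sample
minor allele is per replicate.

The published studies this design emulates used a haplotype pool
distributed with the SKAT software, whose generating model ("calibration
coalescent model" with European-ancestry LD) is not published.  We
therefore calibrated a single-population demographic model to the emergent
summaries those studies report, and the defaults in
`european_growth_demography()` are frozen as part of the study conditions:

* piecewise history in the style of European-growth models (explosive
  recent growth, ancestral bottleneck): diploid sizes 50,000 / 4,604 / 930 /
  12,000 at epoch starts 0 / 205 / 920 / 2,040 generations ago, growth
  rates 0.0116 and 0.00224 per generation in the two recent epochs;
* mutation rate 4.3e-8 per bp per generation, recombination rate 1e-8.

Under these defaults a 3 kb gene at n = 1,000 carries ~33 non-monomorphic
SNVs on average (median ~33–34), with roughly 75–80% of sites at
MAF ≤ 0.03 and just under half of the rare sites being singletons
(MAF = 0.0005, i.e. minor allele count 1).  These targets — not any
particular realization — are what the package pins in a regression test.
The calibration reproduces site-frequency-spectrum and gene-size summaries,
not the exact LD patterns of the original pool, so absolute power numbers
can shift by a few percentage points relative to analyses run on that pool;
rankings between methods are much less sensitive.  `load_haplotype_pool()`
reads an externally exported pool (plain-text matrix with a
`H S region_length` header) for byte-identical reuse when one is available.

# Phenotype model and scenario grid

Quantitative traits follow

    Y = 0.5 x1 + 0.5 x2 + sum_i beta_i g_i + eps,

with `x1 ~ Bin(0.5)`, `x2 ~ N(0, 1)` and standard normal errors.  Causal
variants are drawn uniformly among the gene's rare sites (MAF ≤ 0.03), at
least one per gene, with count `round_half_up(fraction × #rare)`; the
half-up rounding and the floor of one are the package's documented
resolution of a rule stated only as "at least one".  Effect sizes are
`beta_i = c · |log10 MAF_i|` so rarer variants act more strongly; a
`round_half_up(positive_fraction × #causal)` subset gets a positive sign.
The scenario grid (`scenario_grid()`, shipped as YAML) crosses causal
fractions 5/10/20/50%, `c` in 0.6/0.3/0.2 and sign splits 100/0, 80/20,
50/50 — 36 alternative scenarios plus the null (scenario 0, `c = 0`).

The per-gene explained variance is `sum 2 MAF (1 − MAF) beta² / Var(Y)`
over causal sites.  `Var(Y)` is the *empirical* variance of the replicate's
trait vector: the source formula references Var(Y) without fixing
theoretical vs empirical, and the empirical choice yields a well-defined
number per replicate without extra assumptions.  Summaries report the
median and the median absolute deviation across replicates; MAD uses
`stats::mad()`'s standard 1.4826 scaling (the convention of the tables
being emulated is not stated).

For the error-misspecification arm, `eps` can be t4, t8 or standard
log-normal; the log-normal draw is centred by subtracting its mean
`exp(1/2)` so the null intercept stays zero.  A binary-trait generator
(`generate_binary_trait()`) reconstructs the under-specified case-control
arm: logistic disease model on the same linear predictor, intercept solved
numerically for a configurable prevalence (default 0.1), balanced
case-control sampling by rejection.  It is a data generator only — the
association tests in this package are the quantitative-trait tests of the
main study, and `run_scenario()` refuses binary configurations rather than
silently applying a linear model to 0/1 outcomes.

# The four tests

All tests adjust for `(1, x1, x2)`.  With residuals `r` of the
covariate-only fit and `sigma2_hat` its maximum-likelihood residual
variance (score-test convention; the SMT and burden t-tests keep the
unbiased n − 4 divisor of their own four-parameter fits):

* **SMT**: per-SNV OLS Wald t-statistic, `t = beta_hat / SE`, referred to
  `t_{n-4}`; gene-level decision by the minP rule on Bonferroni- or
  Benjamini-Hochberg-adjusted p-values (`p.adjust`; step-up ties need no
  extra handling).  Collinear or constant columns yield missing fits and
  drop out of the adjusted set; duplicated columns are deliberately *not*
  pruned (each is tested).
* **Burden**: Wald t-test of the unweighted per-individual sum of minor
  alleles.
* **SKAT**: `Q = ||W G' r||² / sigma2_hat` with Beta(1, 25)-density MAF
  weights (the linear weighted kernel's conventional default; the shape
  parameters are configurable); the null distribution is the chi-square
  mixture with weights `eigen(W G' P G W)`, `P` the residual projection.
* **SKAT-O**: `Q_rho = (1 − rho) Q_SKAT + rho Q_burden-type` over the grid
  `rho = (0, 0.1², ..., 0.5², 0.5, 1)`.  In the Gaussian linear model the
  decomposition `Q_rho = (1 − rho) kappa + tau(rho) eta0` is exact, with
  `eta0` the chi-square_1 component along the weighted-burden direction and
  `kappa` an independent chi-square mixture (no small-sample variance
  remainder is needed, unlike the logistic case).  The combined p-value is
  the min-p over the grid corrected by one-dimensional integration of
  `P(kappa ≤ min_rho (q_min(rho) − tau(rho) x) / (1 − rho))` against the
  chi-square_1 density.  Per-rho quantiles `q_min(rho)` use the
  kurtosis-matched chi-square approximation — the same choice as the
  reference "optimal.adj" implementation, kept here both for speed and so
  that the null behaviour matches the published calibration; the effect on
  the combined p-value is ~1e-4 near the 0.05 level (larger, up to ~1e-2,
  only far in the centre of the distribution where nothing is decided).

Both inclusion modes of the study — all SNVs, or rare-only (MAF ≤ 0.03) —
apply identically to all four tests.

# Chi-square-mixture tails

`quadform_pvalue()` evaluates `P(sum lambda_j chisq_1 > q)`.  The default
route inverts the characteristic function (Imhof's integral): the
oscillatory integrand is summed over single-oscillation intervals with
Gauss-Kronrod 15 rules, truncation being controlled by the alternating
decay of successive terms past the integrand's single stationary point
plus an envelope bound.  Mixtures of one to three components instead use
exact chi-square convolution (a smooth one/two-dimensional integral after
the substitution `x = u²`).  The requested absolute accuracy is 1e-9 for
standalone calls; the Monte-Carlo driver uses 1e-6, far below any
Monte-Carlo standard error at the replicate counts involved.  Eigenvalues
below 1e-10 of the largest are truncated for stability.  The Liu
moment-matching surrogate is the automatic fallback whenever inversion
misbehaves (flagged in the return value), and a Kuonen saddlepoint route is
available for cross-checks.  Inside the SKAT-O correction integral the
kappa CDF is interpolated from 25 Chebyshev nodes in `sqrt(c)` — smooth in
that variable even when one eigenvalue dominates — which keeps the cost per
SKAT-O evaluation at a fixed small number of inversions; the interpolation
error is well below 1e-6.

# Monte-Carlo design

`run_scenario()` derives one RNG sub-stream per replicate from the root
seed (`child_seed()`, a multiplicative-hash scheme), so results are
reproducible replicate-by-replicate and independent of execution order —
the contract a parallel driver would need, although the shipped driver is a
plain loop.  Degenerate draws (windows with no polymorphic site after
pairing, or no rare site under an alternative scenario) are resampled
within the replicate's stream and counted, keeping denominators at exactly
`m`.  Power and type-I-error estimates carry binomial standard errors
`sqrt(p(1-p)/m)`; SNV-level power pools the causal variants of all
replicates within MAF strata.

The package's default problem sizes are scaled down from the source
study's 10^7-replicate null calibration: the shipped checks use m = 100,000
null replicates (Monte-Carlo SE 0.0007 at the 0.05 level), m = 2,000–10,000
for power, and ~260,000 pooled t-statistics for the estimator-validity
summary.  `m` is configurable up to the original sizes.

# The blood-pressure application stage

Antihypertensive medication right-censors true systolic blood pressure at
the observed value.  `fit_censored_regression()` fits the Tobit model
`SBP = b0 + b1 age + b2 sex + b3 smoke + eps` by maximum likelihood
(`survival::survreg`, Gaussian distribution, medication as the censoring
indicator).  `adjust_phenotype()` then defines the analysis phenotype:
observed minus fitted SBP for untreated individuals, and for treated ones
the conditional expectation of true SBP given that it exceeds the observed
value minus the fitted mean — `sigma_hat · h(z)` with `h` the upper-tail
inverse Mills ratio `phi(z)/(1 − Phi(z))`, evaluated in log-space and
switched to its asymptotic expansion (flagged) when the upper-tail mass
falls below 1e-12.  Gene regions are gene bodies ±5 kb (1-based, floored at
zero; overlaps allowed), and `qc_filter_snvs()` drops SNVs with more than
5% missing calls (strictly greater, so exactly 5% survives), skips
multi-allelic records with a warning (the original handling is unstated;
splitting is deliberately not attempted), imputes residual missing calls to
the per-SNV mean, and applies the all-vs-rare inclusion mode.  The cohort
used in the source analysis is access-restricted, so
`write_synthetic_cohort()` generates a fully synthetic VCF + phenotype +
gene-table fixture for end-to-end tests; nothing beyond column layout is
emulated.

# What passing tests do and do not show

The simulation reproduces the *study conditions*: site-frequency spectrum,
gene sizes, the phenotype model, and the published null calibration of all
five test/correction combinations.  It does not model genotyping error,
population structure, relatedness, covariate-genotype correlation or
non-additive effects, so conclusions about real cohorts inherit the usual
caveats of coalescent-based power studies.  Scenario-level power numbers
on this pool track the published ones to within a few percentage points
(pool-to-pool variation); the method *orderings* — single-marker tests
winning under few strong causal variants, SKAT/SKAT-O under many weak
ones, the unweighted burden test trailing when non-causal common variants
are included — are the stable, reproducible findings.  The one statistic
directly sensitive to the pool's linkage disequilibrium rather than its
site-frequency spectrum is the Bonferroni-minP type I error (its deficit
below the nominal level measures the effective number of independent tests
per gene): this package's pool carries somewhat stronger within-gene
correlation than the original, giving ~0.040 at the 0.05 level where the
published calibration shows 0.044, while the BH-minP and all three MMT
levels agree to well under half a percentage point.

# Known limitations

* The coalescent backend requires a Python interpreter with msprime
  (`options(rarepower.python = ...)` to point at one); pools can otherwise
  only be loaded from files.
* SKAT-O inherits the mild anti-conservatism of the davies/optimal.adj
  construction near alpha = 0.05 that the published calibration also shows.
* The binary-trait arm generates data but has no matching logistic test
  battery; analysing 0/1 traits with the linear-model tests is refused
  rather than approximated.
* Replicates are processed serially; the RNG contract supports a parallel
  driver but none is shipped.
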