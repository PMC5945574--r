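---
title: "Genomic prediction of hybrid rice performance: models, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of hybrid rice performance: models, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridgs)
```

## The problem and the design

Hybrid rice exploits heterosis: an F1 between two inbred parents often
outperforms both. The practical bottleneck is choosing which crosses to
make. With 120 parents on one side and thousands of candidate accessions
on the other, the space of potential hybrids runs into the hundreds of
thousands, and only a tiny fraction can be field-tested. Genomic
selection replaces most of that testing with prediction: a model trained
on a genotyped, phenotyped reference set of hybrids predicts the
performance of every untested cross from parental genotypes alone.

The training design this package is built around is a North Carolina II
factorial: 115 inbred female lines each crossed to 5 male-sterile testers,
giving 575 hybrids, phenotyped for 8 agronomic traits at 2 locations with
2 replicates. Because all parents are (effectively) homozygous, an F1's
genotype is determined by its parents: with additive dosage coding
$-1/0/+1$, the hybrid code at a marker is the mean of the two parental
codes — opposite homozygotes give a heterozygote, identical homozygotes
reproduce the parent. `deduce_hybrid_genotypes()` implements exactly this;
only the parents need sequencing. Residual parental heterozygosity is
handled as an expected dosage of $\pm 0.5$ and flagged, because the
additive models downstream remain unbiased under expectation coding.

## Genotype handling

`read_genotype_table()` accepts biallelic VCF (genotypes from the GT
field, `./.` as missing, multi-allelic records skipped) or a light TSV
dialect with a marker-metadata sidecar, which is far cheaper than VCF for
coded inbred panels. QC follows the design's group-specific rule: a SNP is
dropped if its missing rate is strictly above 20% among the testers or
strictly above 50% among the female lines (`qc_filter_missing()`; "above"
is a strict inequality, so a marker missing in exactly 1 of 5 testers
survives).

`impute_and_encode()` then fixes the coding: the minor allele is
determined from all non-missing calls, $-1$ is the minor-allele
homozygote, and a 50/50 frequency tie is broken lexicographically (the
alphabetically smaller allele is treated as major) so encodings are
reproducible. Remaining missing calls are replaced by the per-marker mode
of the observed codes, ties giving 0. Mode imputation is a deliberate,
deliberately simple choice: it is deterministic, preserves the integer
coding that keeps hybrid deduction and kinship exact, and on inbred panels
with low post-QC missingness its bias is negligible. LD-aware imputation
is out of scope. When two panels must be combined (training parents vs a
candidate panel), `intersect_marker_sets()` matches markers on
chromosome/position with equal allele sets and negates codes where the
ref/alt order is swapped; strand flipping is not attempted, and ambiguous
A/T and C/G swaps are treated like any other swap with a warning.

## GBLUP and its REML engine

The mixed model is
$y = X\beta + \sum_k Z_k \gamma_k + \varepsilon$ with
$\gamma_k \sim N(0, \phi^2/m)$, equivalently
$\mathrm{var}(y) = (K\lambda + I)\sigma^2$ with
$K = \frac1m Z Z^T$ and $\lambda = \phi^2/\sigma^2$. Two details matter:

* **The kinship is the raw marker cross-product.** No column centering, no
  allele-frequency denominator. This keeps the relationship model exactly
  the integrated-out marker-effect model, which is what makes the
  GBLUP/RR-BLUP equivalence hold to machine precision — a property the
  test suite asserts at $10^{-8}$ on random instances.
* **Only the intercept is fitted as a fixed effect.** Hybrids are the
  experimental units and environments are averaged before modelling, so
  there is nothing else to absorb.

`reml_fit()` profiles $\beta$ and $\sigma^2$ out of the restricted
likelihood analytically and maximises the resulting one-dimensional
function of $\lambda$. The search runs in $\theta = \log\lambda$ on
$[\log 10^{-6}, \log 10^6]$ with a safeguarded Newton iteration: the
derivative is bracketed by its sign change, a Newton step that leaves the
bracket is replaced by bisection, and convergence is declared at
$|\Delta\theta| < 10^{-8}$ or $|L'| < 10^{-10}$ (at most 100 iterations).
If the likelihood is monotone on the whole interval the boundary is
reported as the estimate (flagged `boundary = TRUE`), not treated as an
error — under pure noise roughly half the replicates legitimately sit at
the lower bound, a standard property of variance components on the
boundary of the parameter space. A single eigendecomposition of $K$ makes
every likelihood evaluation $O(n)$, which matters because replicated
cross-validation refits the model hundreds of times. The test suite
checks the optimiser against a 2,000-point grid of the same profiled
likelihood and checks the eigen route against dense solves.

Numerical edge handling: eigenvalues of $K$ in $(-10^{-6}\cdot\|K\|, 0)$
are clipped to zero; anything more negative is an error (a genuinely
indefinite kinship indicates corrupted input).

## The other five learners

All five share the `fit_gs_model()` / `predict()` contract and are
interchangeable in cross-validation.

* **LASSO** — coordinate descent on
  $\|y - \mu - Z\gamma\|^2 + \lambda\sum_k|\gamma_k|$ over a 50-point
  log-spaced path from $\lambda_{\max}$ (the smallest penalty with all
  effects zero) down four decades, warm-started; $\lambda$ is chosen by
  internal 5-fold CV minimising mean squared error (the min-CV rule; the
  1-SE alternative was considered and not used). Columns are standardised
  internally and effects back-transformed. On an orthogonal design the
  solution is the soft-threshold closed form at $\lambda/2$, which the
  tests assert, along with agreement with glmnet on a shared objective.
* **BayesB** — marker variances follow a two-component mixture: a point
  mass at zero with probability $\pi$ and a scaled inverse chi-square
  slab $\chi^{-2}(v, S)$ with $v = 4.234$, $S = 0.0429$;
  $\pi \sim \mathrm{Beta}$ parameterised by mean $\pi_0 = 0.5$ and
  concentration $P_0 = 10$ (shapes $\pi_0 P_0$ and $(1-\pi_0)P_0$ — the
  conventional two-shape notation is ambiguous, so the mean/concentration
  reading is fixed here). The Gibbs sampler updates each inclusion
  indicator with the marker effect integrated out (the collapsed update
  mixes far better than naive joint updates), then draws the effect, its
  slab variance, $\pi$, and the residual variance. Chains are
  bit-reproducible given a seed. Defaults: 12,000 iterations, 2,000
  burn-in, thinning 5. Raw genotype codes are used, as the model equation
  implies. One calibration subtlety: because $v$ and $S$ are absolute
  constants, "no signal" only pins the posterior inclusion at its prior
  mean when single-marker evidence is negligible against the slab scale;
  at unit residual variance the collapsed Bayes factor correctly prunes
  null markers below the prior (an Occam effect, not a bug), and the test
  suite asserts both regimes.
* **PLS1** — NIPALS with X-deflation on standardised columns; the
  component count minimises internal 5-fold CV RMSE. Scores are mutually
  orthogonal, and with all components on a full-rank $n > m$ problem the
  fit reproduces OLS — both asserted.
* **SVR** — $\varepsilon$-insensitive support vector regression with the
  Gaussian kernel $\exp(-\|z_i - z_j\|^2 / 2h^2)$, solved by pairwise
  (SMO-style) ascent on the dual in the $\beta = \alpha - \alpha^*$
  parameterisation; each accepted pair step maximises the exact
  piecewise-quadratic gain, so the dual objective increases monotonically;
  termination at KKT violation $10^{-3}$. Defaults, absent any published
  values: $C = 1$, $\varepsilon = 0.1\,\mathrm{sd}(y)$, bandwidth = median
  pairwise distance. The dual optimum is cross-checked against libsvm via
  e1071 on small instances.
* **RKHS** — $y = \mu + \sum_l u_l + \varepsilon$,
  $u_l \sim N(0, K_{h_l}\sigma_l^2)$ with Gaussian kernels
  $K_l = \exp(-D^2/h_l)$ at bandwidths $h_l$ = multiplier × mean squared
  distance, default multipliers $\{0.2, 1, 5\}$ (the published analysis
  names only "multi-kernel", so the grid is this package's choice).
  Sampling runs in each kernel's eigenbasis, making iterations $O(n)$ per
  kernel; variance components get weakly informative scaled-inverse-
  chi-square priors sized from $\mathrm{var}(y)$. With a single kernel and
  the variance ratio held fixed, the posterior mean is computed in closed
  form and equals the GBLUP formula with $K_h$ in place of $K$ — the
  equivalence the tests exploit as an oracle.

## Evaluation machinery

**Predictability** is the Pearson correlation between observed phenotypes
and cross-validation predictions. Each replicate draws a fresh balanced
5-fold partition; every fold is predicted by a model trained on the other
four; and one correlation per replicate is computed on the pooled
out-of-fold predictions of all samples (not averaged over folds — the
pooled reading matches "all parts were predicted once" and keeps one $r$
per replicate for the downstream ANOVA). Twenty replicates are the
reference setting.

**ANOVA and letters.** The per-replicate predictabilities enter a two-way
fixed-effects factorial (trait, method, interaction; replicates as
residual). With 8 traits, 6 methods and 20 replicates the degrees of
freedom are 7, 5, 35 and 912. Multiple comparisons use Tukey's HSD at
$\alpha = 0.05$ on the factor-level means with the ANOVA residual mean
square — the published analysis displays letter groups without naming a
procedure, and HSD is the standard choice behind that display. Letters are
assigned by the sorted-means sweep: maximal runs of mutually
non-significant levels each get a letter, redundant runs are absorbed.

**Subsampling experiments.** `subsample_experiment()` draws repeated
uniform subsets of markers or hybrids, runs one five-fold CV per subset,
and reports mean and sd per size. Desk-scale defaults are marker sizes
{100, 250, 500, 1000, 2000} and 20 selections per size (the reference
protocol of 9 sizes up to $10^6$ markers and 100 selections remains a
parameter choice away); the qualitative signatures — a marker-density
plateau and monotone growth in training size — are what the acceptance
checks assert.

**Heritability.** `estimate_broad_sense_H()` uses expected-mean-squares
estimators from the balanced genotype × environment × replicate ANOVA:
$\hat\sigma^2_\varepsilon = MS_{res}$,
$\hat\sigma^2_{ge} = (MS_{GE} - MS_{res})/r$,
$\hat\sigma^2_g = (MS_G - MS_{GE})/(er)$, negatives clamped to zero, and
$H = \sigma_g^2/(\sigma_g^2 + \sigma_{ge}^2/e + \sigma_\varepsilon^2/(er))$
on the genotype-mean basis. Sums of squares come from the closed-form
group-mean decomposition (exact for balanced data and much faster than a
full linear-model fit at 575 genotypes); `stats::aov` serves as the
independent cross-check in the tests. Unbalanced layouts are rejected
rather than approximated.

## The synthetic study generator

`make_study_bundle()` reproduces the statistical structure the analysis
assumes, not rice biology: fully homozygous parents with minor-allele
frequencies uniform on [0.1, 0.5], optional first-order LD by Markov
allele copying, NC II hybrids by expected-dosage deduction, and
multi-environment phenotypes built as
$y_{ijr} = \mu + g_i + (ge)_{ij} + \varepsilon_{ijr}$. Genetic values are
additive over a random QTL subset (200 by default; a mixture option
emulates major-gene traits) and rescaled so $\sigma_g^2 = 1$ exactly;
noise variances are then set so the broad-sense heritability hits its
target *exactly by construction*, with the non-genetic share split 50/50
between interaction and residual (the reference design reports only $H$,
not the split — the even split is this package's default and is
configurable). The eight default traits use the design's heritability
targets (0.2550–0.8501) and grand means at realistic crop magnitudes
(e.g. 38 g grain yield, 110 cm plant height) so selection gains are
interpretable in percent; all evaluation statistics are location- and
scale-invariant, so the means affect nothing else.

What the generator deliberately does **not** emulate: population
structure and family relatedness beyond the factorial itself, realistic
LD decay, dominance/epistasis (dominance deviations exist as an option but
default to 0 — the reference analysis is additive), genotyping error, and
trait–trait correlations. Passing tests therefore demonstrate that the
machinery is correct and that the qualitative patterns (heritability
ordering, marker plateau, training-size growth) follow from the assumed
model — not that real rice data would yield the same numbers. The
real-data predictabilities of the reference study depend on undeposited
genotypes and phenotypes and are not reproducible here; only its in-text
arithmetic and design counts are checked exactly.

## Randomness and reproducibility

A single master seed is fanned out to named streams (fold draws, subset
draws, simulation, each Gibbs chain) via a deterministic hash, so any
stage can be reproduced in isolation. All samplers use R's RNG —
including the C++ Gibbs kernels — so seeded chains are bit-identical
across runs. `run_full_study()` embeds its config and seed in the report,
making every table regenerable.

## Problem sizes

The reference settings used by the analysis scripts and acceptance checks
are the full simulated design (575 hybrids, 2,000 markers, 8 traits),
5-fold CV with 20 replicates for GBLUP-based experiments, 20 selections
per subsampling size, and 200 simulation replicates for the parameter-
recovery studies; the all-method CV driver defaults to 5 replicates with
shortened MCMC chains (BayesB 3,000/1,000, RKHS 2,000/500), which the
`REPS` variable and chain settings scale back up to the full protocol.

## Known limitations

* Balanced designs only for heritability; no spatial adjustment.
* Mode imputation ignores LD; adequate for low missingness inbred panels,
  wrong tool for sparse genotyping-by-sequencing data.
* The SVR/RKHS hyperparameters of the reference analysis are unknown;
  defaults here are documented choices, not reconstructions.
* Single-trait models throughout; no multi-trait or GxE prediction.
* `gain_curve()`'s 95% interval is a nonparametric bootstrap (1,000
  resamples) over the top-$k$ set — the reference display's interval
  construction is unstated, so this is an explicit package choice.
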