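---
title: "Benchmarking variable selection under heavy collinearity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variable selection under heavy collinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censelect)
```

## The problem

Census-derived neighborhood tables — thousands of tract-level measures of
income, housing, employment, education — are a natural covariate source for
studying health disparities, but they are awkward for variable selection:
distributions are skewed, many variables carry an excess of exact zeros, and
large groups of variables are nearly interchangeable (absolute correlations
above 0.95 are common). An agnostic scan of such a table against a health
outcome must therefore separate a handful of truly associated variables from
hundreds of near-duplicates and confounded proxies.

`censelect` implements a simulation benchmark for this setting. It generates
covariate tables with known structure, plants a sparse signal of known
strength, runs a panel of selection strategies, and scores each one on how
well it recovers the planted truth. The panel covers the approaches a
practitioner would plausibly reach for: mass univariable testing with
Bonferroni correction, the lasso and elastic net with cross-validated
penalties, the sparse group lasso on correlation-derived variable clusters,
random forests and bagging with variable-importance confidence intervals,
and Bayesian additive regression trees (BART) with permutation-calibrated
inclusion-proportion thresholds.

## The generating model

Covariates come from a Gaussian copula. A latent multivariate normal vector
carries the dependence: within each declared block all pairwise latent
correlations equal the block's target (0.97 for "marked" collinearity, 0.5
for moderate), and off-block correlations are zero by default. Each latent
column is then pushed through a monotone marginal transform — identity
(gaussian), exponential (log-normal), or a zero-inflated log-normal that
places a point mass at zero — so the observed table inherits the latent rank
correlations while showing census-like skewness and zero excess. Entries are
knocked out completely at random at a small rate, median-imputed, and every
column is standardized to mean 0, standard deviation 1 (n − 1 denominator),
in that order: imputation and standardization happen once on the full
matrix, before any discovery/validation split.

Outcomes depend on 10 true variables with a common standardized effect
size β: 5 drawn from the pool of variables whose maximum absolute
correlation with any other variable exceeds 0.95, and 5 from the pool whose
correlations all stay below 0.6. Binary outcomes follow
logit(E(Y)) = β′X_T with no intercept (prevalence 1/2); continuous outcomes
follow E(Y) = β′X_T with standard normal errors.

β is not a free dial. It is calibrated so that a single univariable Wald
test at two-sided level 5×10⁻⁵ (the Bonferroni threshold for 1000 tests)
reaches at least 80% power at the full sample size, and then rounded *up*
to two decimals so the power guarantee survives rounding. With n = 2000
this gives β = 0.22 for binary outcomes (standard error 1/√(n·0.25) at
prevalence 0.5) and β = 0.11 for continuous outcomes (standard error 1/√n):

```{r}
calibrate_effect_size("binary", n = 2000)
calibrate_effect_size("continuous", n = 2000)
```

Chaining the discovery-stage power (two thirds of the data, α = 5×10⁻⁵)
with the validation-stage power (the remaining third, α = 0.05) gives the
expected per-variable detection rate for the univariable baseline:

```{r}
wald_power(0.22, n = 1333, family = "binary", alpha = 5e-5) *
  wald_power(0.22, n = 667, family = "binary", alpha = 0.05)
```

about 39%. Realized detection rates can sit far from this number for
individual variables: correlated truths confound one another's univariable
effects, and a truth whose marginal effect is attenuated toward zero is
essentially undetectable by marginal screening no matter the sample size.
The test suite reproduces this on a constructed pair of truths correlated
at −0.6, whose univariable effects shrink to 0.4β.

## What the generator does and does not emulate

Defaults were chosen once, as a realistic census-like profile, and are not
tuned to test outcomes: p = 1000 variables, n = 2000 observations, eight
5-variable blocks at |ρ| = 0.97 and ten 3-variable blocks at 0.5, marginals
40% gaussian / 30% log-normal / 30% zero-inflated with a 0.3 zero mass, and
2% missingness. Marginal shapes are assigned per block — every member of a
collinearity block shares one shape — because near-duplicate census
measures are near-duplicate *kinds* of measure, and because pushing two
latent variables through different monotone transforms shrinks their
observed Pearson correlation well below the latent target, which would
hollow out the >0.95 eligibility pool the truth picker draws from. The
zero mass matters for fidelity: ties at zero (and ties
introduced by median imputation) attenuate rank correlations, and a 0.3
zero probability keeps realized within-block Spearman correlations within
±0.05 of the latent target at these sample sizes, which is the tolerance
the generator promises.

The generator does not reproduce real census marginal distributions, the
spatial autocorrelation of tract-level data, or outcome models with
interactions or nonlinearities. Passing benchmarks here therefore says how
methods behave under calibrated sparse linear signal and block collinearity
— the mechanism the benchmark isolates — not how they will rank on any
particular registry linkage.

## The selection panel

Every method sees the same discovery set (a random two-thirds split) and
returns a set of candidate variables; candidates are then re-tested on the
held-out third — by default one univariable model per candidate, keeping
p < 0.05 — and only validated candidates are scored.

* **UNIV-BFN** — one univariable model per variable, selecting Wald
  p < 0.05/p.
* **LASSO-MIN / LASSO-1SE** — `glmnet` lasso with λ at the CV minimum or at
  the one-standard-error rule; **ELNET-MIN / ELNET-1SE** — the same with a
  grid search over the elastic-net mixing parameter α from 0.05 to 0.95 in
  steps of 0.05, sharing one fold assignment across the whole grid.
* **HCLST-CORR-SGL / HCLST-BOOT-SGL** — variables are clustered on the
  distance 1 − |Spearman ρ| with complete linkage; groups are either the
  maximal sets merged strictly below height 0.2 (so within-group |ρ| > 0.8;
  a pair at exactly 0.8 stays apart) or the maximal non-overlapping
  dendrogram nodes whose exact member set recurs in at least 95% of
  bootstrap re-clusterings. The groups feed the package's own sparse group
  lasso solver.
* **RF / BAGGING** — `ranger` ensembles (per-split candidate counts
  ⌊p/3⌋ for regression, ⌊√p⌋ for classification, or all p for bagging)
  with out-of-bag permutation importance; standard errors come from a
  delete-d jackknife over 100 refits on subsamples of size n^0.75, and a
  variable is selected when its 100·(1 − α/p)% interval (99.995% at
  α = 0.05, p = 1000) lies entirely above zero.
* **BART-LOCAL / BART-GLOBALSE / BART-GLOBALMAX** — the package's compact
  BART sampler records each variable's share of splitting rules across
  posterior draws; refitting on permuted outcomes yields a null
  distribution of these inclusion proportions, and the three thresholds
  (per-variable 95% null quantile; null mean plus a globally calibrated
  multiple of the null SD; the 95% quantile of the per-permutation maximum)
  trade selection power against family-wise control.

## Scoring

Strict scoring counts a true positive only for an exact member of the
truth set. Relaxed scoring accepts a *surrogate* — a non-true variable
whose absolute Pearson correlation with a truth exceeds 0.8 (strictly;
Spearman available by flag) — as identifying that truth, counts each truth
at most once, and removes all surrogates from the false-positive pool. Both
accountings feed the F2 score,

F2 = 5·TP / (5·TP + 4·FN + FP),

which up-weights sensitivity over precision, matching the view that in
hypothesis-generating scans a missed true association costs more than a
false lead. Replicate-level F2 values are averaged arithmetically across
replicates; the summary table also reports the F2 of the mean counts, a
slightly different aggregate, since the two can disagree in the second
decimal.

## Numerical choices

* **Sparse group lasso.** The solver minimizes deviance plus
  λ[(1 − mix)·Σ_g √p_g·‖β_g‖₂ + mix·‖β‖₁] by blockwise proximal gradient
  descent: one BLAS gradient per sweep screens zero groups through the
  group-level KKT condition, active groups are updated with the composite
  proximal operator (elementwise soft-threshold, then group shrinkage)
  using the exact group Lipschitz constant, with FISTA acceleration and
  adaptive restart inside each block; gaussian singleton groups have a
  closed-form update. Convergence is declared when no coefficient moves
  more than 1e-7 in a full sweep; the path uses warm starts. mix defaults
  to 0.95, and λ is chosen by 10-fold CV at the minimum error (no 1SE rule
  for the SGL). The λ path is 20 log-spaced values from the analytic λ_max
  (found per group by bisection on the KKT condition) down to 0.1·λ_max —
  the convention of standard SGL implementations. Stopping the path well
  above zero is deliberate: with near-duplicate blocks at |ρ| = 0.97 a
  nearly unpenalized logistic fit is close to unidentifiable, and path
  tails below 0.1·λ_max buy no additional selections at enormous cost.
* **Lasso / elastic net.** 100 λ values down to 0.001·λ_max, 10-fold CV,
  matrices pre-standardized so `standardize = FALSE`. Coefficients below
  1e-10 in magnitude count as zero when reading off selections, so exact
  duplicate columns do not produce phantom selections from numerical dust.
* **BART.** 20 trees (small ensembles sharpen inclusion proportions for
  selection), 1000 burn-in and 1000 kept draws, 100 permutation refits,
  α = 0.05; grow/prune proposals with the standard depth prior
  (0.95·(1 + d)⁻²), the rule prior charging 1/(p·n_cut) per split, normal
  leaf prior 0.5/(k√m) on the rescaled outcome (3/(k√m) probit for binary),
  and a scaled inverse-χ² noise prior calibrated at the 0.9 quantile.
  Draws with zero total splits contribute a uniform 1/p profile. All
  draws run on R's RNG, so a seed makes runs bit-for-bit reproducible.
* **Bootstrap cluster stability.** The root of the dendrogram is never a
  candidate cluster (every dendrogram contains it, so its stability is
  trivially 1). Resampled replicates that produce constant columns get
  those columns placed at maximal distance rather than erroring. This
  stability-proportion criterion is a deliberate simplification of
  multiscale bootstrap p-value methods.
* **Ties and degenerate cases.** Spearman correlations use average ranks;
  degenerate null columns in the BART global-SE rule fall back to their
  mean as the threshold; empty selections validate to empty sets; method
  failures inside the benchmark loop are logged per replicate and excluded
  from that method's means rather than imputed or made fatal.
* **Splits and seeds.** The discovery set has exactly round(2n/3)
  observations. One master seed spawns the covariate draw, the truth draw,
  and three independent per-replicate streams (outcome, split, method
  seeds), so a benchmark is reproducible from a single integer.

## Problem sizes used by the test suite

The full study design (p = 1000, n = 2000, 500 replicates) is the package
default but not what the tests run. The suite exercises the same code paths
at sizes chosen for a single CPU: method-ordering and null-calibration
checks use p = 200, n = 600 with 50–200 outcome replicates (with a 50-value
λ path down to 0.01·λ_max and the same 10 folds), and the BART null
calibration uses p = 50, n = 300 with 50 permutations. At these sizes the
qualitative contrasts of interest — elastic net finding more strict true
positives than the conservative lasso, the conservative lasso admitting
fewer strict false positives, the clustered sparse group lasso leading on
relaxed F2, BART's global-max threshold selecting almost nothing — are
stable, while the exact summary-table numbers are not expected to transfer
across problem sizes.

## Limitations

The benchmark inherits the assumptions of its generator: linear sparse
signal, equal effect sizes, exchangeable observations, missingness
completely at random. The bootstrap cluster criterion is a stability
proportion, not an approximately-unbiased p-value. The BART sampler is a
compact implementation — grow and prune moves only, no swap or change
proposals — adequate for inclusion-proportion selection rules but not a
drop-in replacement for full-featured BART software. Confidence intervals
for permutation importance use a normal approximation with jackknife
standard errors; at small n the subsampling size n^0.75 becomes fragile and
the functions refuse to run rather than return noise.
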