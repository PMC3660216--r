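---
title: "Why normalized expression data hit a power ceiling"
author: "normpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why normalized expression data hit a power ceiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normpower)
```

## The question

Quantile normalization (QUANT) and rank normalization (RANK) are
standard pre-processing steps for expression arrays. QUANT replaces each
array's values by a reference array of rank-wise averaged order
statistics, so every array ends up with the same empirical distribution;
RANK replaces each value by its fractional within-array rank. Both
remove array-level technical variation, and both are often applied
before per-gene two-sample tests.

The phenomenon this package studies: with a fixed number `n` of arrays
per group, the power of differential-expression tests on QUANT- or
RANK-normalized data converges to a limit *strictly below 100%* as the
true effect size grows. Strong biology cannot substitute for sample
size. `normpower` implements the simulation model, the normalizations,
the tests, and the distribution theory that explains the ceiling, so the
effect can be measured and predicted rather than taken on faith.

## The simulation model

`simulate_simu()` draws a genes-by-arrays matrix of log2 expressions:

* `m` genes on `2n` arrays (groups A and B, `n` each);
* noise marginally `N(0, sigma^2)` with a common pairwise gene–gene
  correlation `rho` within each array, generated by the exact
  single-factor construction `sigma * (sqrt(rho) * Z_j +
  sqrt(1 - rho) * eps_ij)` with one shared standard normal `Z_j` per
  array — the standard representation of an equicorrelation matrix;
* group-B means all zero (every test in the package is shift-invariant,
  so this loses no generality), and group-A means `e_up` for the first
  `m1_up` genes, `e_down` for the next `m1_down`, zero otherwise. Truth
  labels are assigned in that deterministic block order, which keeps the
  bookkeeping trivial and is exchangeable under the model.

Defaults mirror a childhood-leukemia-scale array study: `m = 1000`
genes, `sigma = 0.35` and `rho = 0.9` on the log2 scale (values of the
magnitude observed on real leukemia arrays), 60 up- and 40
down-regulated genes among 1000, and `n` of 5 or 10. Effect sizes are
swept over `e = 0.2, 0.4, ..., 3.6`; at `sigma = 0.35`, `e = 3.6` is a
ten-standard-deviation separation, i.e. essentially complete biological
separation of the groups.

`simulate_bio_like()` relaxes the constant-effect assumption: each gene
carries its own effect size (sign = direction), plus an optional common
increment, emulating designs whose effect profile was recorded from real
data. `random_gene_effects()` draws such a profile with
`|Normal(0.5, 0.25)|` magnitudes — a convenience default of this
package, chosen to give sub-sigma to multi-sigma effects; no conclusion
in the test suite depends on that distribution.

What the generator does *not* emulate: non-Gaussian noise, non-additive
(e.g. intensity-dependent) technical artifacts, heteroscedastic genes,
and block-structured correlation. Passing tests therefore demonstrate
the normalization-induced ceiling under the idealized correlated
Gaussian model, not the full messiness of real arrays; the mechanism,
however, only requires that normalization mixes DEG and non-DEG values,
which is distribution-free.

## Normalizations and tests

`quantile_normalize()` computes the reference array `q_r` = mean of the
r-th smallest value across all `2n` arrays (both groups pooled, as the
procedure is applied blind to phenotype) and substitutes entries by
rank. `rank_normalize()` maps values to `rank/m`, rank 1 = smallest.
Continuous simulated data are tie-free almost surely; for user data,
ties receive average ranks (RANK) or the mean of the reference entries
spanning the tied rank range (QUANT), matching the dominant convention
in existing implementations. `identity_normalize()` is the no-op
comparator, so "no normalization" flows through the same pipeline.

`t_test_genes()` is the equal-variance pooled t-test,
`t = sqrt(n/2) * (mean_A - mean_B) / pooled_sd` with
`pooled_sd = sqrt((s_A^2 + s_B^2)/2)` and `2n - 2` degrees of freedom —
the pooled form, not Welch, because the theory tracks exactly this
statistic. `wilcoxon_genes()` uses the exact rank-sum null for
`n <= 10` (ties fall back to the normal approximation and are flagged).
`n_test_genes()` is a permutation energy test: statistic
`2*mean|a-b| - mean|a-a'| - mean|b-b'|` over all ordered value pairs,
p-value `(1 + #{perm >= obs}) / (1 + n_perm)` under random relabeling,
with the same permutations applied to every gene. Default
`n_perm = 1000`; the smallest achievable p-value is `1/(n_perm + 1)`,
and a warning fires when that cannot resolve the requested level.

P-values are Bonferroni-adjusted (`min(1, m*p)`), and a gene is declared
differentially expressed when the adjusted p-value is *strictly* below
`alpha = 0.05`, controlling the family-wise error rate. Benjamini–
Hochberg is available as an option but is not used by any experiment
driver.

## The experiments

`power_curve()` replays the replicated design: for each effect size it
draws `n_replicates` datasets (default 20, matching the scale at which
one-SD error bars are informative) and applies every normalization and
test *to the same data*, so method contrasts are paired. It reports
mean/SD of true and false positives. `median_abs_t_curve()` (default
200 replicates) pools DEG `|t|` values across replicates — pooling
rather than per-replicate medians, for stability at small `m1` — and
`t_density_estimate()` returns Gaussian-kernel densities of pooled DEG
t-statistics (Silverman's rule-of-thumb bandwidth; nothing downstream
is sensitive to reasonable bandwidth choices except mode *counting*,
for which `density_modes()` exposes a relative height threshold,
default 5% of the peak, to ignore kernel ripple). `estimate_fwer()`
measures the fraction of null replicates with any rejection.

Per-replicate seeds are derived from the design's root seed as
`seed + replicate index` (offset by condition), so every tibble the
drivers return is bit-identical under a fixed root seed.

Typical problem sizes, chosen so the full suite replays in minutes on a
laptop core: 20 replicates for power curves, 200 for median and density
curves, `m = 1000`. All are arguments, not constants.

## Why the ceiling appears: mixture theory

After QUANT, an up-regulated gene's group-A values occupy top ranks in
every array once `e` is large, but its group-B ranks remain those of a
null gene. Conditional on where the gene's `n` group-B ranks fall, the
t-statistic takes one of three forms:

* all group-B ranks in the top `m1_up` block (probability
  `(m1_up/m)^n`): numerator and denominator both O(1) — a central t;
* all in the middle `m0` block or all in the bottom `m1_down` block
  (probability `(m0/m)^n + (m1_down/m)^n`): numerator grows linearly in
  `e`, denominator stays O(1) — a noncentral t;
* mixed ranks (the remaining probability): the *denominator also*
  grows, because the gene's group-B values then straddle reference
  segments that are `O(e)` apart — a doubly noncentral t, the law of
  `(Z + gamma) / sqrt(chisq_nu(lambda)/nu)`.

`mixture_weights()` evaluates these occupancy probabilities
(`mixture_weights(1000, 60, 40, 10)` gives a central weight of
`0.06^10 ≈ 6e-13` — negligible, which is why only interior and outer
modes are visible in density plots). The doubly noncentral component
has all moments bounded in `e`, which caps `|t|` and hence power.

`t_density_doubly_noncentral()` integrates the conditional normal
density against the noncentral chi-square law of the denominator.
Numerically this is done by trapezoid quadrature on the log scale of
the chi-square variable, restricted to the interval holding all but
1e-14 of the mass per tail, with node doubling until successive
estimates agree within `abs_tol` (default 1e-8): adaptive quadrature on
the raw scale silently loses the chi-square bulk when `lambda` reaches
the hundreds, which is exactly the regime the overlays need. The
implementation was validated against 10^6 Monte-Carlo draws of the
defining ratio (Kolmogorov–Smirnov distance ~5e-4).

The theory fixes `gamma` and `lambda` only up to proportionality in
`e`, so for overlays `calibrate_mixture_params()` estimates them from
simulation: each DEG-replicate case is classified by its observed
group-B rank occupancy; the baseline SD `sigma0` comes from the pooled
variance of the noncentral cases, `gamma` from their mean normalized
difference, and `lambda` from the variance inflation of the mixed
cases. This is calibration, not derivation — the package makes no claim
to closed-form constants.

A practical note on comparing the calibrated mixture with simulated
density estimates: the kernel estimator localizes a mode only to about
one bandwidth (≈3 t-units at the overlay design, where the outer mode
sits near |t| ≈ 52), so mode agreement is asserted at that resolution.
Sub-bandwidth agreement is not a meaningful target for a smoothed
estimate.

For RANK, the limit is cleaner: once DEGs saturate the extreme ranks in
group A, fractional ranks are uniform on fixed sub-intervals
(`rank_asymptotic_support()`), group-B ranks stay uniform on (0, 1), and
the expected group difference converges to `1/2 - m1_up/(2m)` for
up-regulated genes (`rank_expected_difference()`), independent of `e`.

## Numerical and degenerate-input choices

* Zero pooled SD with zero mean difference gives `t = 0, p = 1`; with a
  non-zero difference, `t = ±Inf, p = 0`, flagged in a `degenerate`
  column rather than erroring, so pipelines survive pathological genes.
* `alpha = 0` is accepted (rejects nothing), making the degenerate FWER
  check expressible.
* Bonferroni uses `stats::p.adjust()`; rank computations use base
  `rank()` with the tie conventions above; exactness thresholds for the
  Wilcoxon test follow `stats::wilcox.test()`.
* Permutation p-values use the add-one convention
  `(1 + #) / (1 + n_perm)`, which is valid (never anti-conservative)
  and never returns 0.

## Known limitations

* Equal group sizes only; the theory's `sqrt(n/2)` scaling assumes a
  balanced design.
* The SIMU-BIO-style generator is a Gaussian stand-in for resampled
  real arrays; it reproduces heterogeneous effect structure but not
  non-additive noise.
* `gamma` and `lambda` are calibrated, so mixture overlays inherit
  Monte-Carlo error from the calibration replicates.
* Homogeneous correlation only in the tested configurations;
  block-heterogeneous `rho` is expressible by composing
  `equicorrelated_noise()` calls but is not exercised by the suite.

## Reproducibility

Every experiment driver takes its randomness from the design's root
seed and derives per-replicate streams deterministically.
`scripts/acceptance.R --seed S --out F` recomputes the two summary
numbers (null FWER of the pipeline; QUANT power at the top of the
effect grid with n = 5) from scratch under root seed `S`.
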