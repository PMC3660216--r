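# normpower

Quantile and rank normalization are routine pre-processing steps for
microarray and other genomic expression data: quantile normalization
(QUANT) forces every array to share one empirical distribution, and rank
normalization (RANK) replaces each value by its fractional within-array
rank. Both procedures have a counter-intuitive consequence for
differential expression analysis: **with a fixed, small number of arrays
per group, the power of per-gene tests on normalized data plateaus
strictly below 100% no matter how strong the true differentiation is**.
One cannot trade effect size for sample size.

`normpower` is a simulation and theory toolkit for studying this
phenomenon. It is aimed at statisticians and bioinformaticians designing
expression studies or choosing normalization procedures, and provides:

* an equicorrelated Gaussian simulator of two-group log2-expression
  experiments (`simu_design()`, `simulate_simu()`, `simulate_bio_like()`),
* quantile, rank and identity normalization (`quantile_normalize()`,
  `rank_normalize()`, `identity_normalize()`),
* per-gene tests — pooled two-sample t, Wilcoxon rank-sum, and a
  permutation energy (N-) test — with Bonferroni family-wise error
  control (`t_test_genes()`, `adjust_gene_pvalues()`, `confusion_counts()`),
* replicated experiment drivers for power curves, median |t| curves,
  t-statistic density estimates and empirical FWER (`power_curve()`,
  `median_abs_t_curve()`, `t_density_estimate()`, `estimate_fwer()`),
  each returning a tidy tibble with a ggplot2 `autoplot()` method,
* the distribution theory that predicts the plateau: the mixture of
  central, noncentral and doubly noncentral t distributions followed by
  quantile-normalized DEG t-statistics (`mixture_weights()`,
  `t_density_doubly_noncentral()`, `mixture_density()`,
  `calibrate_mixture_params()`), and the uniform large-effect limits of
  rank-normalized expressions (`rank_expected_difference()`,
  `rank_asymptotic_support()`).

## The model in brief

For gene `i` on array `j` in phenotype group `c ∈ {A, B}` (n arrays per
group), log2 expressions are

```
y_ij^c = mu_i^c + eps_ij^c,   mu_i^A = e_i,  mu_i^B = 0,
```

with `e_i = e+ > 0` for up-regulated genes, `e- < 0` for down-regulated
ones, 0 otherwise; the noise is marginally `N(0, sigma^2)` with common
gene–gene correlation `rho` within each array. Each gene is tested with
the pooled two-sample t-statistic

```
t_i = sqrt(n/2) * (mean_A - mean_B) / pooled_sd,   df = 2n - 2,
```

with Bonferroni-adjusted two-sided p-values thresholded at `alpha = 0.05`.
On raw data, `|t_i|` grows linearly in the effect size and power reaches
1. After quantile normalization, the normalized mean difference *and* the
pooled SD both grow at most linearly in the effect size, so the
t-statistic of a differentially expressed gene converges to a mixture

```
f ≈ (m1+/m)^n f_t + [(m0/m)^n + (m1-/m)^n] f_T(gamma)
    + [1 - (m0/m)^n - (m1+/m)^n - (m1-/m)^n] f_T(gamma, lambda)
```

of central, noncentral and doubly noncentral t distributions whose
doubly noncentral part has bounded moments — hence the plateau. Rank
normalization removes the effect size entirely in the large-effect
limit: fractional ranks become uniform on fixed sub-intervals of [0, 1].

## Worked example

```r
library(normpower)

design <- simu_design(m = 1000, m1_up = 60, m1_down = 40, n = 5,
                      sigma = 0.35, rho = 0.9, seed = 42)
pc <- power_curve(design, e_grid = seq(0.2, 3.6, by = 0.2),
                  methods = c("none", "quant", "rank"),
                  n_replicates = 20)
subset(as.data.frame(pc), e == 3.6,
       select = c(method, tp_mean, tp_sd, fp_mean))
#>    method tp_mean    tp_sd fp_mean
#> 52   none  100.00 0.000000     0.0
#> 53  quant   59.80 3.764096     0.0
#> 54   rank    6.55 2.704285     0.2
autoplot(pc)
```

At the largest simulated effect size (`e = 3.6`, i.e. about 10 noise
standard deviations), the un-normalized analysis recovers all 100 truly
differentially expressed genes in every replicate, while the same test
on quantile-normalized data finds on average 59.8 of them (about 6.5
after rank normalization) — the power plateau. False positives stay near
zero throughout, so the ceiling is not a type-I-error artifact. At small
effect sizes the ordering reverses: normalization removes the shared
array factor (90% of the variance here) and *improves* power.

The mixture theory can be overlaid on simulation:

```r
d4 <- simu_design(m = 1000, m1_up = 60, m1_down = 40, n = 10,
                  sigma = 0.35, rho = 0.9, e_up = 4, e_down = -4,
                  seed = 42)
params <- calibrate_mixture_params(d4, n_replicates = 200)
dens <- t_density_estimate(d4, e_values = 4, methods = "quant",
                           n_replicates = 200)
plot_mixture_overlay(dens[dens$method == "quant", ], params)
```

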