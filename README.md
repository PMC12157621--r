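# varhet

Variance heterogeneity (VH) and bimodality testing for grouped biomedical
measurements, with a simulation engine for study design.

## The problem

Standard group comparisons target the mean. But when a treatment helps only
a subset of patients, or a cohort contains two latent molecular subgroups, a
mean test can see nothing while the *spread* changes dramatically: unequal
variance between groups, or a bimodal distribution within one group. varhet
is for biostatisticians and computational biologists who want to treat that
spread as signal:

* **Two-group dispersion tests** — permutation tests on the statistic
  `T = |log(D1/D2)|` where `D` is the SD, the median absolute deviation, or
  the Gini mean difference `GMD = 2/(n(n-1)) Σ_{i<j} |x_i − x_j|`, with the
  add-one p-value rule `p = (1 + #{T* ≥ T})/(B + 1)`; plus
  Levene/Brown–Forsythe, ANOVA, Welch t, and the two-sample
  Kolmogorov–Smirnov test, all on a tidy `group`/`value` data frame.
* **Bimodality detection** — EM fits of K-component normal / log-normal /
  Weibull mixtures; the parametric **bootstrap likelihood-ratio test** for
  1 vs 2 components (`2(ℓ₁ − ℓ₀)` against its simulated null); **Hartigan's
  dip statistic** (computed exactly, Monte-Carlo calibrated against the
  uniform); and the **bimodality coefficient**
  `BC = (g₁² + 1)/(g₂ + 3(n−1)²/((n−2)(n−3)))` with its 5/9 uniform
  benchmark.
* **Power / FPR engine** — Monte-Carlo power and false-positive-rate
  estimation for any of these tests across sample sizes, under parametric
  designs or by bootstrapped subsampling of pilot data.
* **Twin-discordance screen** — per-feature cotwin deltas (higher-covariate
  member minus lower), top-k variance filtering, per-feature bootstrap LRT,
  Benjamini–Hochberg FDR control and a minority-mode-proportion filter.

## Worked example

Does a cohort of 200 measurements hide two modes, and which group drives
the extra spread?

```r
library(varhet)

spec <- mixture_spec(
  list(dist_spec("normal", mean = 0, sd = 1),
       dist_spec("normal", mean = 4, sd = 1)),
  weights = c(0.3, 0.7)
)
x <- sample_mixture(spec, 200, seed = 1)$value

fit <- em_fit(x, "normal", K = 2, seed = 1)
tidy(fit)
#> # A tibble: 2 × 6
#>   component weight   mean    sd mean_natural sd_natural
#>       <int>  <dbl>  <dbl> <dbl>        <dbl>      <dbl>
#> 1         1  0.295 -0.263 0.802       -0.263      0.802
#> 2         2  0.705  4.02  1.06         4.02       1.06

bootstrap_lrt(x, "normal", n_boot = 100, seed = 1)
#> <bootstrap_lrt> normal mixture, K = 1 vs 2
#>   LRT = 94.656, p = 0.009901 (100 bootstraps)

dip_test(x, n_null = 999, seed = 1)$p_value
#> [1] 0.002

# two-group dispersion: same location, 2x spread
d <- tibble::tibble(
  group = rep(c("a", "b"), each = 60),
  value = c(dist_sample(dist_spec("normal", mean = 0, sd = 1), 60, seed = 2),
            dist_sample(dist_spec("normal", mean = 0, sd = 2), 60, seed = 3))
)
perm_dispersion_test(d, metric = "gini", n_perm = 999, seed = 4)
#> # A tibble: 1 × 5
#>   method    statistic p_value n_resamples  seed
#>   <chr>         <dbl>   <dbl>       <int> <int>
#> 1 perm_gini     0.460   0.001         999     4
```

The mixture fit recovers the planted 30/70 split and the 4-SD mode gap; the
bootstrap LRT p-value of 0.0099 (= 1/101, the smallest value 100 bootstraps
can produce) and the dip p-value of 0.002 both reject unimodality; the
permutation test attributes p = 0.001 to the realised Gini dispersion ratio
`exp(0.460) ≈ 1.6` between the two groups (simulated with a 2× SD effect at
n = 60, where the sample ratio sits below the population one).

Power for a planned study:

```r
pd <- power_design("two_group",
  baseline = dist_spec("normal", mean = 0, sd = 1),
  effect   = effect_spec(mean_effect = 0, variance_effect = 2),
  n_per_group = seq(40, 100, 20), n_sim = 500,
  test = "perm_sd", test_args = list(n_perm = 200), seed = 1
)
estimate_power(pd)[, c("n", "power", "ci_low", "ci_high")]
#> # A tibble: 4 × 4
#>       n power ci_low ci_high
#>   <int> <dbl>  <dbl>   <dbl>
#> 1    40 0.978  0.961   0.988
#> 2    60 0.998  0.989   1.00
#> 3    80 1      0.992   1
#> 4   100 1      0.992   1
```

A doubling of the SD is already detected almost surely at 40 per group; the
interesting design questions live at smaller fold-changes, which is what the
simulation grid is for.

A command-line interface (`exec/varhet`) wraps the same functions:
`varhet test`, `varhet bimodality`, `varhet power`, `varhet screen-twins`,
`varhet eda`, `varhet fixture`; every run writes its results as CSV plus a
JSON manifest recording inputs, settings and seed.

## Documentation

The methods vignette
(`vignettes/variance-heterogeneity-methods.Rmd`) explains the models,
numerical choices (EM restarts and variance floor, dip computation,
p-value granularity under BH), what the synthetic fixtures do and do not
emulate, and known limitations.
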