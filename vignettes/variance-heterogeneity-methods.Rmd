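---
title: "Detecting variance heterogeneity and bimodality with varhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variance heterogeneity and bimodality with varhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varhet)
library(dplyr)
```

## Why test spread, not just location

Most group comparisons in biomedicine ask whether means differ. But when a
treatment works in a subset of patients, or a cohort hides two latent
subpopulations (a high- and a low-expressing mode of a gene, short- and
long-surviving patients), the signal appears as *excess or unequal spread*:
variance heterogeneity (VH) between groups, or bimodality within one group.
varhet treats spread as signal. It provides

1. two-group tests for dispersion differences (permutation tests on robust
   dispersion statistics, Levene/Brown-Forsythe) alongside mean tests (ANOVA,
   Welch t) and a whole-distribution test (Kolmogorov–Smirnov);
2. one-cohort bimodality detection (finite-mixture bootstrap LRT, Hartigan's
   dip, the bimodality coefficient);
3. a Monte-Carlo engine that estimates the power and false positive rate of
   any of those tests under a user-specified study design; and
4. an end-to-end screen for bimodal cotwin discordance in expression
   matrices.

## The models

### Parametric families and effects

Four families cover the data types the workflows target: normal (logged
expression), log-normal, Weibull (survival times, uncensored here), and beta
(methylation-like fractions). A two-group design is a baseline
`dist_spec` plus an `effect_spec`: an additive shift of the natural-scale
mean and a multiplicative fold-change of the standard deviation. The
fold-change multiplies the SD rather than the variance — a "2× spread"
request doubles the SD and quadruples the variance — because fold-change in
SD units is how effect sizes are usually communicated, and `×1` is then the
identity on both scales. For non-normal families the shifted/rescaled group
is obtained by re-solving the family parameters from the target mean and SD
(log-normal and beta in closed form, Weibull by root-solving the coefficient
of variation in the shape). Targets outside the family's feasible set raise
an error; nothing is clipped silently.

### Permutation dispersion tests

For two groups with dispersions $D_1, D_2$ (SD, unscaled MAD, or Gini mean
difference), the observed statistic is

$$T = \lvert \log(D_1 / D_2) \rvert,$$

which is symmetric in the group labels and invariant to the measurement
scale. Group labels are permuted $B$ times (default $B = 1000$) and

$$p = \frac{1 + \#\{T^\ast \ge T\}}{B + 1},$$

the add-one rule, so $p \ge 1/(B+1)$ and the test is valid under
exchangeability. A zero-dispersion group (all values tied) is mapped to the
smallest representable positive number with a warning, which preserves the
extremeness ordering without producing NaN; two zero-dispersion groups are
reported as degenerate. The Gini mean difference is computed in
$O(n \log n)$ via the sorted-order identity
$\mathrm{GMD} = \tfrac{2}{n(n-1)} \sum_i (2i - n - 1)\, x_{(i)}$.

### Mixture fits and the bootstrap LRT

`em_fit()` fits $K$-component mixtures by EM for the normal, log-normal
(normal EM on logs, log-likelihood mapped back through the Jacobian) and
Weibull families. The M-step is the weighted MLE per component; the weighted
Weibull shape solves the profile score equation by safeguarded Newton with a
bisection fallback (the score is strictly increasing in the shape).
Components are always reported sorted by ascending natural-scale mean, which
fixes label switching once for classification, screening and fixtures alike.

Numerical choices worth knowing:

* **tolerance and iterations**: relative log-likelihood change below `1e-8`
  or 1000 iterations;
* **variance floor**: a normal component SD below $10^{-6}\,\mathrm{sd}(x)$,
  or a weight below $10^{-4}$, marks the run as collapsed — this is the
  likelihood singularity, not a fit;
* **initialisation and restarts**: the first run seeds component $j$ from
  the $j$-th quantile block of the sorted data (deterministic; a k-means
  partition is the alternative); further restarts draw random data points
  as centres. With several restarts the package uses the short-EM strategy:
  every initialisation runs at most 25 iterations and only the most
  promising run continues to convergence. If every scheduled restart
  collapses, a bounded reserve of fresh random initialisations is tried.
  On null (unimodal) data EM is attracted to the singularity often enough
  that this reserve matters, and occasionally *no* interior K-component
  optimum is reachable at all; the fit then falls back to K identical
  components — the single-component MLE embedded in the K-component space —
  whose likelihood equals the K = 1 likelihood exactly, so the bootstrap
  LRT sees zero (never inflated) evidence for extra components from
  singularity artefacts;
* **tie-break**: posterior ties in `classify_modes()` go to the lower-mean
  component.

The number-of-modes decision uses the parametric bootstrap likelihood-ratio
test: fit $K_0$ (default 1) and $K_1$ (default 2) components, simulate
`n_boot` datasets from the fitted null, refit both models on each, and
compare $2(\ell_1 - \ell_0)$ against the bootstrap distribution with the
add-one rule. The classical $\chi^2$ asymptotics fail for mixtures (the null
lies on the parameter-space boundary), which is why the bootstrap is the
field's standard. A negative observed LRT can arise from finite EM
tolerance; it is clamped to zero, with a warning beyond $10^{-6}$. Weibull
mixtures here are for uncensored values; applying them to survival times
ignores the censoring structure, which reproduces the common practice this
package accompanies and is a documented limitation, not an endorsement.

### Non-mixture bimodality detectors

The **bimodality coefficient** is
$\mathrm{BC} = (g_1^2 + 1) / \big(g_2 + 3(n-1)^2 / ((n-2)(n-3))\big)$ with
bias-adjusted sample skewness $g_1$ and excess kurtosis $g_2$. The uniform
scores $5/9$, the conventional reference; BC is reported as a statistic next
to that benchmark and never silently converted into a p-value.

The **dip statistic** is the smallest supremum distance between the
empirical CDF and any unimodal CDF. varhet computes it exactly by bisection
on the distance $t$: for each placement of the mode between adjacent
distinct order statistics, the constraints decouple into a convex and a
concave half linked through the junction value, and each half's feasibility
(and its extreme attainable junction value) has a closed form via support
lines of the ECDF band. The implementation is validated in the test suite
against an independent linear-programming oracle that solves the defining
minimax problem directly. `dip_test()` calibrates the dip against uniform
samples of the same size — the standard calibration distribution — by Monte
Carlo (default 2000 draws) rather than interpolated lookup tables, which
keeps the null transparent and seed-reproducible. Note the dip is
*conservative* on normal data under this calibration: its false positive
rate sits well below the nominal level, which costs power at small
separations. Silverman's critical-bandwidth and excess-mass tests are
natural extension points; the mixture LRT plus dip and BC cover the
mixture-based and shape-based axes used here.

### Power engine

`estimate_power()` simulates `n_sim` datasets per sample size under one of
three designs — two unimodal groups linked by an effect, one cohort drawn
from a mixture, or two mixtures — applies the chosen test, and reports the
rejection proportion with a Wilson 95% interval. Under a null design the
same number *is* the false positive rate; there is deliberately one engine
with two labels. Defaults mirror common usage in this literature: sample
sizes 40–100 in steps of 10, `n_sim = 1000`, `alpha = 0.05`, 100 bootstraps
inside the mixture LRT. For the bimodality coefficient, which has no
p-value, "rejection" means exceeding the 5/9 uniform benchmark.

`empirical_power_subsample()` is the assumption-free counterpart: it
resamples a pilot dataset (with replacement, because target sizes may reach
or exceed the pilot size) at each target size and reports the same
rejection-fraction table. Agreement between the two estimates on pilot data
drawn from the fitted model is itself a useful model check, and is exercised
as such in the acceptance suite. One caveat applies: the subsampling
estimate conditions on a *single* pilot realisation, so away from saturated
power it inherits that pilot's luck — a few-percentage-point offset from
the parametric curve at the smallest target sizes is expected behaviour,
not a defect, and it shrinks as power approaches 1.

**Reproducibility contract**: every replicate derives its own seed from the
root seed via an integer hash keyed by replicate index and sample size
(`derive_seed()`). Adding replicates or extending the sample-size grid never
changes results already computed; scheduling cannot perturb anything because
no state is shared across replicates.

## The twin-discordance screen

For monozygotic twin pairs discordant for a covariate such as BMI, the
per-feature discordance $\Delta$ = (value in the higher-covariate twin) −
(value in the lower-covariate twin) removes shared genetic and much shared
environmental signal. Features unrelated to the covariate scatter around
$\Delta \approx 0$; covariate-coupled features in a *subset* of pairs show a
bimodal $\Delta$. The screen (`compute_deltas()` →
`top_variable_features()` → `screen_bimodal_features()`):

1. orients every pair by the covariate (ties keep the declared order and are
   flagged), requiring both members present;
2. ranks features by the SD of $\Delta$ across pairs and keeps the top $k$
   (default 4000, the conventional depth for genome-wide versions of this
   screen);
3. runs the normal-family bootstrap LRT per feature, adjusts p-values by
   Benjamini–Hochberg across all tested features, and excludes features
   whose minority mode is smaller than 10% of samples — a guard against
   outlier-driven "modes". The default FDR level is 5%.

The minority-mode filter uses the fitted minority mixing weight, the most
direct reading of "a mode comprising under 10% of samples"; the
classified-label fraction is available as an option. Expression input is
assumed already normalised/log-scaled; upstream normalisation is out of
scope and emulated by the fixture generator.

The p-value granularity of the bootstrap matters here: with $B$ bootstraps
the smallest achievable raw p is $1/(B+1)$, and after BH adjustment over $m$
features with $m_1$ true signals the smallest adjusted p is roughly
$\tfrac{1}{B+1} \cdot \tfrac{m}{m_1}$. $B$ must therefore comfortably exceed
$m / (q \cdot m_1)$ for FDR level $q$ — one reason genome-wide screens use
$B = 10{,}000$. The function default is $B = 200$, a desk-scale setting for
the fixture sizes used in the tests; scale it up for real screens.

## What the synthetic fixtures emulate — and what they don't

`generate_fixture()` produces the three study shapes with known truth:
two-group tables from a baseline-plus-effect design; single-cohort mixture
draws with true component labels; and a features × pairs delta matrix
(defaults: 146 pairs, 4000 features, 292 planted bimodal features) in which
planted features mix a majority mode at 0 with a minority mode displaced by
4 noise-SD units (random sign, minority weight uniform on [0.1, 0.5]) and
null features are pure noise around 0. Identical seeds give byte-identical
files.

The twin fixture reproduces the *decision problem* (a minority of bimodal
features among unimodal ones at matched sample size), not real expression
data: features are independent, noise is exactly normal with equal variance,
and modes are clean displacements. Passing the planted-truth tests therefore
demonstrates that the screen recovers the signal it defines under its own
assumptions — correlated features, heavy tails and array artefacts in real
data can only degrade the operating characteristics, and the FDR guarantee
of BH formally relies on independence-like conditions that real expression
matrices violate.

## Problem sizes in the validation suite

The packaged tests and the acceptance script run at desk scale, chosen so
the full suite completes on one CPU in minutes while keeping every check
statistically meaningful: null calibrations use 1000 replicates with nested
resampling reduced (200 permutations, 100 bootstraps, 100 dip null draws);
the planted twin screen uses 500 features / 50 planted / 146 pairs with 200
bootstraps; the all-null FDR check uses 100 features over 20 seeds; power
curves use a few hundred simulations per sample size. Genome-scale runs
simply scale the same entry points up.

## Known limitations

* Weibull mixtures ignore censoring; do not read the survival-time fits as
  survival analysis.
* The dip's uniform-null Monte-Carlo calibration is conservative for
  light-tailed unimodal data (this is a property of the dip itself).
* The mixture machinery fits 1-vs-2 components by default; mode counts
  beyond 2 are supported by `em_fit()`/`bic()` but not by the screening
  workflow.
* `apply_effect()` refuses infeasible mean/SD targets rather than projecting
  them; power grids over extreme effects must stay inside the family's
  moment space.
* Between-feature dependence is ignored by the BH step in the screen, as in
  the analyses this package mirrors.
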