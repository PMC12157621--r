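Package: varhet
Title: Variance Heterogeneity and Bimodality Testing with Simulation-Based Power Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects variance heterogeneity and bimodality in grouped biomedical
    measurements. Provides permutation tests on dispersion statistics (standard
    deviation, median absolute deviation, Gini mean difference), classical
    variance and mean tests (Levene/Brown-Forsythe, ANOVA, Welch t,
    Kolmogorov-Smirnov), finite-mixture EM fitting for normal, log-normal and
    Weibull families with a parametric bootstrap likelihood-ratio test for the
    number of components, the bimodality coefficient and Hartigan's dip test,
    a Monte-Carlo engine for power and false-positive-rate estimation across
    study designs, and an end-to-end screen for bimodal cotwin-discordance in
    expression matrices. Includes exploratory summaries (Cullen-Frey
    skewness/kurtosis plane) and a synthetic fixture generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    boot,
    car,
    fitdistrplus,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
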