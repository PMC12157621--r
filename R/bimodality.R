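#' Bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with bias-adjusted
#' sample skewness `g1` and excess kurtosis `g2`. Larger values suggest
#' bimodality; the uniform distribution scores `5/9 ~ 0.556` (the
#' conventional benchmark), a normal tends to `1/3`, and a symmetric
#' two-point distribution approaches 1. The coefficient is reported as a
#' statistic with the 5/9 reference, never auto-converted into a p-value.
#'
#' @param values Numeric vector, `n >= 4`, non-constant.
#' @return A positive scalar.
#' @examples
#' bimodality_coefficient(runif(5000)) # ~ 5/9
#' @export
bimodality_coefficient <- function(values) {
  values <- check_values(values, min_n = 4)
  n <- length(values)
  if (stats::var(values) == 0) {
    abort("values are constant; bimodality coefficient undefined",
      class = "varhet_degenerate_error"
    )
  }
  sk <- sample_skew_kurt(values)
  (sk[["g1"]]^2 + 1) / (sk[["g2"]] + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# bias-adjusted sample skewness (G1) and excess kurtosis (G2)
sample_skew_kurt <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2 - 3
  g1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * b2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  c(g1 = g1, g2 = g2)
}

#' Hartigan-Hartigan dip statistic
#'
#' The smallest supremum distance between the empirical CDF and any unimodal
#' CDF. Values near the lower bound `1/(2n)` indicate compatibility with
#' unimodality; an equal mixture of two separated point masses attains the
#' upper limit 1/4. Invariant under increasing affine transforms of the data.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return The dip, in `[1/(2n), 1/2]` (values above 1/4 arise only for
#'   heavily tied, atom-like data).
#' @examples
#' dip_statistic(c(rep(0, 50), rep(1, 50))) # 0.25
#' @export
dip_statistic <- function(values) {
  values <- check_values(values, min_n = 4)
  dip_cpp(sort.int(values, method = "quick"))
}

#' Monte-Carlo dip test of unimodality
#'
#' Compares the observed dip with dips of uniform samples of the same size —
#' the standard calibration distribution for the dip — using `n_null`
#' Monte-Carlo draws and the add-one p-value rule.
#'
#' @param values Numeric vector, `n >= 4`.
#' @param n_null Number of uniform null samples.
#' @param seed Optional integer seed.
#' @return A one-row `vh_test` tibble.
#' @examples
#' x <- c(rnorm(100), rnorm(100, 6))
#' dip_test(x, n_null = 199, seed = 1)
#' @export
dip_test <- function(values, n_null = 2000, seed = NULL) {
  values <- check_values(values, min_n = 4)
  n <- length(values)
  d_obs <- dip_cpp(sort.int(values, method = "quick"))
  d_null <- with_seed(seed, {
    vapply(seq_len(n_null), function(b) dip_cpp(sort.int(runif(n))), numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_null + 1)
  new_test_result("dip", d_obs, p, n_resamples = n_null, seed = seed)
}

#' Run any bimodality detector through one dispatch point
#'
#' A single interface over the mixture bootstrap-LRT (normal, log-normal or
#' Weibull family), the Monte-Carlo dip test, and the bimodality coefficient.
#' Mixture and dip methods return a p-value; the bare coefficient returns the
#' statistic with its 5/9 uniform benchmark instead.
#'
#' @param values Numeric data vector.
#' @param method One of `"mix_lrt_normal"`, `"mix_lrt_lognormal"`,
#'   `"mix_lrt_weibull"`, `"dip"`, `"bc"`.
#' @param n_boot Bootstrap replicates for the mixture methods.
#' @param n_null Null draws for the dip test.
#' @param seed Optional integer seed.
#' @param ... Further arguments passed to [bootstrap_lrt()].
#' @return A one-row tibble with columns `method`, `statistic`, `p_value`,
#'   `n_resamples`, `seed` and `threshold_reference` (5/9 for `"bc"`, `NA`
#'   otherwise).
#' @export
test_bimodality <- function(values,
                            method = c(
                              "mix_lrt_normal", "mix_lrt_lognormal",
                              "mix_lrt_weibull", "dip", "bc"
                            ),
                            n_boot = 100, n_null = 2000, seed = NULL, ...) {
  method <- match.arg(method)
  res <- switch(method,
    mix_lrt_normal = tidy(bootstrap_lrt(values, "normal", n_boot = n_boot, seed = seed, ...)),
    mix_lrt_lognormal = tidy(bootstrap_lrt(values, "lognormal", n_boot = n_boot, seed = seed, ...)),
    mix_lrt_weibull = tidy(bootstrap_lrt(values, "weibull", n_boot = n_boot, seed = seed, ...)),
    dip = tidy(dip_test(values, n_null = n_null, seed = seed)),
    bc = tibble::tibble(
      method = "bc",
      statistic = bimodality_coefficient(values),
      p_value = NA_real_,
      n_resamples = NA_integer_,
      seed = as.integer(seed %||% NA_integer_)
    )
  )
  res$threshold_reference <- if (method == "bc") 5 / 9 else NA_real_
  res
}
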