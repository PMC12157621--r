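#' Wilson score confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return Named numeric vector `c(low, high)`, always inside `[0, 1]`.
#' @examples
#' wilson_interval(50, 1000)
#' @export
wilson_interval <- function(k, n, level = 0.95) {
  stopifnot(k >= 0, k <= n, n > 0)
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the interval always contains p-hat; guard the boundary cases against
  # floating-point round-off
  low <- if (k == 0) 0 else min(max(0, centre - half), p)
  high <- if (k == n) 1 else max(min(1, centre + half), p)
  c(low = low, high = high)
}

two_group_tests <- c(
  "perm_sd", "perm_mad", "perm_gini", "levene", "brown_forsythe",
  "anova", "welch_t", "perm_mean", "ks"
)
one_group_tests <- c(
  "mix_lrt_normal", "mix_lrt_lognormal", "mix_lrt_weibull", "dip", "bc"
)

# returns TRUE for rejection; BC has no p-value, so its rejection rule is
# exceeding the 5/9 uniform benchmark
run_power_test <- function(test, data, alpha, args) {
  if (test %in% two_group_tests) {
    res <- switch(test,
      perm_sd = perm_dispersion_test(data, "sd", n_perm = args$n_perm %||% 200),
      perm_mad = perm_dispersion_test(data, "mad", n_perm = args$n_perm %||% 200),
      perm_gini = perm_dispersion_test(data, "gini", n_perm = args$n_perm %||% 200),
      levene = levene_test(data, center = "mean"),
      brown_forsythe = levene_test(data, center = "median"),
      anova = mean_test(data, "anova"),
      welch_t = mean_test(data, "welch_t"),
      perm_mean = mean_test(data, "perm_mean", n_perm = args$n_perm %||% 200),
      ks = ks_two_sample(data)
    )
    return(res$p_value < alpha)
  }
  if (test == "bc") {
    return(bimodality_coefficient(data) > 5 / 9)
  }
  if (test == "dip") {
    res <- dip_test(data, n_null = args$n_null %||% 200)
    return(res$p_value < alpha)
  }
  family <- sub("mix_lrt_", "", test)
  res <- bootstrap_lrt(data, family,
    n_boot = args$n_boot %||% 100,
    n_restarts = args$n_restarts %||% 5,
    tol = args$tol %||% 1e-8
  )
  res$p_value < alpha
}

#' Describe a power/false-positive-rate simulation design
#'
#' Three study designs are supported, mirroring the simulation modules of the
#' accompanying analysis workflow:
#' * `"two_group"`: a unimodal baseline [dist_spec()] versus the same family
#'   shifted/rescaled by an [effect_spec()]; paired with a two-group test.
#'   The identity effect turns the estimate into a false positive rate.
#' * `"one_group_bimodality"`: a single cohort drawn from `baseline` (a
#'   [mixture_spec()], or a [dist_spec()] for null runs); paired with a
#'   bimodality test.
#' * `"two_group_mixture"`: `baseline` versus `comparison`, both
#'   [mixture_spec()] objects; paired with a two-group test.
#'
#' @param design Design label (see above).
#' @param baseline A [dist_spec()] or [mixture_spec()].
#' @param effect An [effect_spec()] (two_group design only).
#' @param comparison Second [mixture_spec()] (two_group_mixture design only).
#' @param n_per_group Integer vector of per-group sample sizes; the default
#'   grid is 40-100 by 10.
#' @param alpha Significance level.
#' @param n_sim Simulated datasets per sample size.
#' @param test Test identifier; one of `r paste(two_group_tests, collapse=", ")`
#'   for two-group designs, or `r paste(one_group_tests, collapse=", ")` for
#'   the bimodality design.
#' @param test_args Named list of test settings (`n_perm`, `n_boot`,
#'   `n_null`, `n_restarts`).
#' @param seed Root seed; every replicate uses a derived substream, keyed by
#'   the sample size, so extending the grid never changes existing rows.
#' @return A `power_design` object for [estimate_power()].
#' @export
power_design <- function(design = c("two_group", "one_group_bimodality", "two_group_mixture"),
                         baseline, effect = NULL, comparison = NULL,
                         n_per_group = seq(40, 100, by = 10), alpha = 0.05,
                         n_sim = 1000, test, test_args = list(), seed = NULL) {
  design <- match.arg(design)
  if (any(n_per_group < 5) || n_sim < 1 || alpha <= 0 || alpha >= 1) {
    abort("need n_per_group >= 5, n_sim >= 1 and alpha in (0, 1)",
      class = "varhet_parameter_error"
    )
  }
  ok <- switch(design,
    two_group = is_dist_spec(baseline) && test %in% two_group_tests,
    one_group_bimodality = (is_mixture_spec(baseline) || is_dist_spec(baseline)) &&
      test %in% one_group_tests,
    two_group_mixture = is_mixture_spec(baseline) && is_mixture_spec(comparison) &&
      test %in% two_group_tests
  )
  if (!isTRUE(ok)) {
    abort(paste0("test '", test, "' or baseline type incompatible with design '", design, "'"),
      class = "varhet_usage_error"
    )
  }
  if (design == "two_group") {
    effect <- effect %||% effect_spec(0, 1)
    # fail early on infeasible effects
    apply_effect(baseline, effect)
  }
  structure(
    list(
      design = design, baseline = baseline, effect = effect,
      comparison = comparison, n_per_group = as.integer(n_per_group),
      alpha = alpha, n_sim = as.integer(n_sim), test = test,
      test_args = test_args, seed = seed
    ),
    class = "power_design"
  )
}

#' Estimate power (or FPR) by Monte-Carlo simulation
#'
#' For each requested sample size, simulates `n_sim` datasets under the
#' design, applies the chosen test, and reports the rejection proportion at
#' level `alpha` with a Wilson 95% interval. Under a null design (identity
#' effect, unimodal baseline, or identical mixtures) the reported "power" is
#' the false positive rate — one engine, two labels.
#'
#' @param design A [power_design()].
#' @return A tibble of class `power_result` with one row per sample size:
#'   `design`, `test`, `n`, `n_sim`, `alpha`, `rejections`, `power`,
#'   `ci_low`, `ci_high`, `mean_time`, `seed`.
#' @examples
#' pd <- power_design("two_group",
#'   baseline = dist_spec("normal", mean = 0, sd = 1),
#'   effect = effect_spec(0, 2), n_per_group = 50,
#'   n_sim = 50, test = "levene", seed = 1
#' )
#' estimate_power(pd)
#' @export
estimate_power <- function(design) {
  stopifnot(inherits(design, "power_design"))
  des <- design
  rows <- lapply(des$n_per_group, function(n) {
    t0 <- proc.time()[["elapsed"]]
    rej <- 0L
    for (s in seq_len(des$n_sim)) {
      seed_s <- if (is.null(des$seed)) NULL else derive_seed(des$seed, s, stream = n)
      rej <- rej + as.integer(with_seed(seed_s, simulate_and_test(des, n)))
    }
    elapsed <- proc.time()[["elapsed"]] - t0
    ci <- wilson_interval(rej, des$n_sim)
    tibble::tibble(
      design = des$design, test = des$test, n = n,
      n_sim = des$n_sim, alpha = des$alpha, rejections = rej,
      power = rej / des$n_sim, ci_low = ci[["low"]], ci_high = ci[["high"]],
      mean_time = elapsed / des$n_sim,
      seed = as.integer(des$seed %||% NA_integer_)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_result", class(out))
  out
}

simulate_and_test <- function(design, n) {
  if (design$design == "two_group") {
    shifted <- apply_effect(design$baseline, design$effect)
    data <- tibble::tibble(
      group = rep(c("g1", "g2"), each = n),
      value = c(dist_sample(design$baseline, n), dist_sample(shifted, n))
    )
  } else if (design$design == "two_group_mixture") {
    data <- tibble::tibble(
      group = rep(c("g1", "g2"), each = n),
      value = c(rmixture(design$baseline, n), rmixture(design$comparison, n))
    )
  } else {
    data <- if (is_mixture_spec(design$baseline)) {
      rmixture(design$baseline, n)
    } else {
      dist_sample(design$baseline, n)
    }
  }
  run_power_test(design$test, data, design$alpha, design$test_args)
}

#' Empirical power by bootstrapped subsampling of pilot data
#'
#' Estimates power without distributional assumptions: for each target sample
#' size, draws `n_boot` with-replacement resamples of that size from the
#' pilot data, applies the test, and reports the rejection fraction with a
#' Wilson interval. With-replacement resampling is used (rather than
#' subsampling without replacement) because target sizes may approach or
#' exceed the pilot size.
#'
#' @param pilot Numeric vector (one-group/bimodality tests) or a
#'   `group`/`value` data frame (two-group tests; resampling is stratified
#'   within group).
#' @param n_targets Integer vector of target sample sizes (per group, if
#'   grouped).
#' @param test Test identifier, as in [power_design()].
#' @param n_boot Resamples per target size.
#' @param alpha Significance level.
#' @param test_args Named list of test settings.
#' @param seed Root seed (per-resample substreams, keyed by target size).
#' @return A `power_result` tibble, one row per target size.
#' @export
empirical_power_subsample <- function(pilot, n_targets, test, n_boot = 200,
                                      alpha = 0.05, test_args = list(),
                                      seed = NULL) {
  grouped <- is.data.frame(pilot)
  if (grouped) {
    pilot <- as_sample_set(pilot)
    if (test %in% one_group_tests) {
      abort("grouped pilot data needs a two-group test", class = "varhet_usage_error")
    }
    groups <- split(pilot$value, pilot$group)
  } else {
    pilot <- check_values(pilot, min_n = 5)
    if (test %in% two_group_tests) {
      abort("ungrouped pilot data needs a one-group test", class = "varhet_usage_error")
    }
  }
  rows <- lapply(as.integer(n_targets), function(n) {
    t0 <- proc.time()[["elapsed"]]
    rej <- 0L
    for (b in seq_len(n_boot)) {
      seed_b <- if (is.null(seed)) NULL else derive_seed(seed, b, stream = n)
      rej <- rej + as.integer(with_seed(seed_b, {
        data <- if (grouped) {
          tibble::tibble(
            group = rep(names(groups), each = n),
            value = c(
              sample(groups[[1]], n, replace = TRUE),
              sample(groups[[2]], n, replace = TRUE)
            )
          )
        } else {
          sample(pilot, n, replace = TRUE)
        }
        run_power_test(test, data, alpha, test_args)
      }))
    }
    elapsed <- proc.time()[["elapsed"]] - t0
    ci <- wilson_interval(rej, n_boot)
    tibble::tibble(
      design = "empirical_subsample", test = test, n = n, n_sim = n_boot,
      alpha = alpha, rejections = rej, power = rej / n_boot,
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      mean_time = elapsed / n_boot, seed = as.integer(seed %||% NA_integer_)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_result", class(out))
  out
}

#' @export
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n, y = .data$power,
    colour = .data$test, group = .data$test
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high, fill = .data$test),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = unique(object$alpha),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "sample size per group", y = "rejection proportion") +
    ggplot2::theme_minimal()
}
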