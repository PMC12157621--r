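#' Exploratory distribution summary with a Cullen-Frey bootstrap cloud
#'
#' Computes moment summaries (bias-adjusted skewness and excess kurtosis) and
#' the sample's position in the Cullen-Frey plane (`x = skewness^2`,
#' `y = kurtosis`, non-excess), together with `n_boot` bootstrap replicates
#' of that position to visualise estimation uncertainty. The plane is the
#' standard triage device for candidate families: a normal sits at (0, 3),
#' a uniform at (0, 1.8), and an exponential at (4, 9).
#'
#' @param values Numeric vector, `n >= 4`, non-constant.
#' @param n_boot Number of bootstrap replicates for the cloud (0 = none).
#' @param seed Optional integer seed.
#' @return An object of class `eda_summary`: a one-row tibble with columns
#'   `n`, `mean`, `sd`, `skewness`, `kurtosis_excess`, `cf_x`, `cf_y`, with
#'   the bootstrap cloud tibble in `attr(, "boot")`.
#' @examples
#' eda_summary(rnorm(500), n_boot = 50, seed = 1)
#' @export
eda_summary <- function(values, n_boot = 100, seed = NULL) {
  values <- check_values(values, min_n = 4)
  if (stats::var(values) == 0) {
    abort("values are constant; moments are degenerate",
      class = "varhet_degenerate_error"
    )
  }
  n <- length(values)
  sk <- sample_skew_kurt(values)
  out <- tibble::tibble(
    n = n, mean = mean(values), sd = stats::sd(values),
    skewness = sk[["g1"]], kurtosis_excess = sk[["g2"]],
    cf_x = sk[["g1"]]^2, cf_y = sk[["g2"]] + 3
  )
  boot <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      rows <- vapply(seq_len(n_boot), function(b) {
        sample_skew_kurt(sample(values, n, replace = TRUE))
      }, numeric(2))
      tibble::tibble(
        skewness = rows["g1", ], kurtosis_excess = rows["g2", ],
        cf_x = rows["g1", ]^2, cf_y = rows["g2", ] + 3
      )
    })
  }
  attr(out, "boot") <- boot
  class(out) <- c("eda_summary", class(out))
  out
}

#' @export
tidy.eda_summary <- function(x, ...) tibble::as_tibble(unclass(x))

#' Cullen-Frey plot
#'
#' Skewness-squared versus kurtosis for the observation (and its bootstrap
#' cloud, if present), with the classical reference marks: normal (0, 3),
#' uniform (0, 1.8), exponential (4, 9), plus the log-normal and gamma lines.
#' Following convention the kurtosis axis is displayed reversed.
#'
#' @param x An [eda_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_cullen_frey <- function(x, ...) {
  stopifnot(inherits(x, "eda_summary"))
  boot <- attr(x, "boot")
  refs <- tibble::tibble(
    cf_x = c(0, 0, 4),
    cf_y = c(3, 1.8, 9),
    label = c("normal", "uniform", "exponential")
  )
  # parametric curves traced over their shape parameter
  sh <- exp(seq(log(0.2), log(20), length.out = 120))
  gamma_line <- tibble::tibble(cf_x = (2 / sqrt(sh))^2, cf_y = 3 + 6 / sh)
  s2 <- seq(0.01, 1.2, length.out = 120)
  ew <- exp(s2)
  lnorm_line <- tibble::tibble(
    cf_x = ((ew + 2) * sqrt(ew - 1))^2,
    cf_y = exp(4 * s2) + 2 * exp(3 * s2) + 3 * exp(2 * s2) - 3
  )
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$cf_x, y = .data$cf_y))
  if (!is.null(boot)) {
    p <- p + ggplot2::geom_point(data = boot, colour = "orange", alpha = 0.4, size = 1)
  }
  p +
    ggplot2::geom_line(data = gamma_line, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(data = lnorm_line, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point(data = refs, shape = 8, size = 3, colour = "grey30") +
    ggplot2::geom_text(
      data = refs, ggplot2::aes(label = .data$label),
      nudge_y = -0.25, size = 3, colour = "grey30"
    ) +
    ggplot2::geom_point(colour = "blue", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "skewness squared", y = "kurtosis") +
    ggplot2::theme_minimal()
}
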