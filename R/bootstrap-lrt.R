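#' Parametric bootstrap likelihood-ratio test for the number of components
#'
#' Tests a K0-component mixture (default: one component, i.e. unimodality)
#' against a K1-component alternative. Both models are fitted to the data by
#' [em_fit()]; the observed statistic is `2 * (logLik1 - logLik0)`. Its null
#' distribution is estimated by the parametric bootstrap: `n_boot` datasets
#' of the original size are simulated from the fitted K0 model, both models
#' are refitted to each, and the p-value is the add-one-corrected exceedance
#' proportion `(1 + #{LRT* >= LRT_obs}) / (n_boot + 1)`.
#'
#' Bootstrap refits reuse the EM settings of the observed fit, each replicate
#' under its own derived seed. A replicate whose refit collapses is redrawn
#' (up to `max_retries` times) and the event is recorded in the result.
#' Negative observed statistics from numerical jitter are clamped to zero
#' (with a warning beyond `1e-6`).
#'
#' @inheritParams em_fit
#' @param K0,K1 Component counts under the null and alternative; `K0 < K1`.
#' @param n_boot Number of parametric bootstrap replicates.
#' @param max_retries Redraw budget per degenerate bootstrap replicate.
#' @return An object of class `bootstrap_lrt` with the statistic, p-value,
#'   both fits, the bootstrap statistics and the retry count.
#' @examples
#' spec <- mixture_spec(
#'   list(
#'     dist_spec("normal", mean = 0, sd = 1),
#'     dist_spec("normal", mean = 4, sd = 1)
#'   ),
#'   weights = c(0.5, 0.5)
#' )
#' x <- sample_mixture(spec, 120, seed = 2)$value
#' blrt <- bootstrap_lrt(x, "normal", n_boot = 30, seed = 2)
#' tidy(blrt)
#' @export
bootstrap_lrt <- function(values, family = c("normal", "lognormal", "weibull"),
                          K0 = 1, K1 = 2, n_boot = 100, seed = NULL,
                          init = c("quantile", "kmeans"), n_restarts = 5,
                          tol = 1e-8, max_iter = 1000, max_retries = 3) {
  family <- match.arg(family)
  init <- match.arg(init)
  if (K0 >= K1) abort("K0 must be smaller than K1", class = "varhet_parameter_error")
  values <- check_values(values, min_n = 5 * K1)
  check_support(values, family)

  fit0 <- em_fit(values, family, K0,
    init = init, n_restarts = n_restarts,
    tol = tol, max_iter = max_iter,
    seed = if (is.null(seed)) NULL else derive_seed(seed, 0L, stream = 1L)
  )
  fit1 <- em_fit(values, family, K1,
    init = init, n_restarts = n_restarts,
    tol = tol, max_iter = max_iter,
    seed = if (is.null(seed)) NULL else derive_seed(seed, 0L, stream = 2L)
  )
  lrt <- 2 * (fit1$log_likelihood - fit0$log_likelihood)
  if (lrt < -1e-6) {
    warn(paste0("negative LRT statistic (", format(lrt), ") clamped to 0"))
  }
  lrt <- max(lrt, 0)

  null_spec <- fit_as_mixture_spec(fit0)
  n <- length(values)
  boot_stats <- numeric(n_boot)
  retries <- 0L
  for (b in seq_len(n_boot)) {
    stat <- NA_real_
    for (attempt in 0:max_retries) {
      seed_b <- if (is.null(seed)) NULL else {
        derive_seed(seed, b, stream = 10L + attempt)
      }
      y <- with_seed(seed_b, rmixture(null_spec, n))
      stat <- tryCatch(
        {
          c0 <- em_core(y, family, K0, init, n_restarts, tol, max_iter,
            seed = seed_b
          )
          c1 <- em_core(y, family, K1, init, n_restarts, tol, max_iter,
            seed = seed_b
          )
          max(0, 2 * (c1$loglik - c0$loglik))
        },
        varhet_degenerate_fit_error = function(e) NA_real_,
        varhet_degenerate_error = function(e) NA_real_
      )
      if (!is.na(stat)) break
      retries <- retries + 1L
    }
    if (is.na(stat)) {
      abort("bootstrap replicate kept collapsing after retries",
        class = "varhet_degenerate_fit_error"
      )
    }
    boot_stats[b] <- stat
  }
  p <- (1 + sum(boot_stats >= lrt)) / (n_boot + 1)

  structure(
    list(
      lrt_statistic = lrt, p_value = p, n_boot = n_boot,
      null_fit = fit0, alt_fit = fit1, boot_stats = boot_stats,
      seed = seed, n_retries = retries, family = family, K0 = K0, K1 = K1
    ),
    class = "bootstrap_lrt"
  )
}

fit_as_mixture_spec <- function(fit) {
  mixture_spec(fit$components, fit$weights)
}

#' @export
print.bootstrap_lrt <- function(x, ...) {
  cat("<bootstrap_lrt> ", x$family, " mixture, K = ", x$K0, " vs ", x$K1, "\n",
    "  LRT = ", format(x$lrt_statistic, digits = 5),
    ", p = ", format(x$p_value, digits = 4),
    " (", x$n_boot, " bootstraps)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.bootstrap_lrt <- function(x, ...) {
  tibble::tibble(
    method = paste0("mix_lrt_", x$family),
    statistic = x$lrt_statistic,
    p_value = x$p_value,
    n_resamples = x$n_boot,
    seed = x$seed %||% NA_integer_
  )
}

#' @export
glance.bootstrap_lrt <- function(x, ...) {
  tibble::tibble(
    family = x$family, K0 = x$K0, K1 = x$K1,
    lrt_statistic = x$lrt_statistic, p_value = x$p_value,
    n_boot = x$n_boot, n_retries = x$n_retries,
    bic_null = bic(x$null_fit), bic_alt = bic(x$alt_fit)
  )
}
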