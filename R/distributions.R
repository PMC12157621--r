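#' Parametric distribution specification
#'
#' A lightweight container for the four families used throughout the package:
#' normal, log-normal, Weibull and beta. Parameters are validated on
#' construction; all downstream simulation, moment and fitting code consumes
#' these objects.
#'
#' Parameter names by family:
#' * `normal`: `mean`, `sd` (sd > 0)
#' * `lognormal`: `meanlog`, `sdlog` (sdlog > 0)
#' * `weibull`: `shape`, `scale` (both > 0)
#' * `beta`: `shape1`, `shape2` (both > 0)
#'
#' @param family One of `"normal"`, `"lognormal"`, `"weibull"`, `"beta"`.
#' @param ... Named family parameters (see above).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("normal", mean = 0, sd = 1)
#' dist_spec("weibull", shape = 2, scale = 1)
#' @export
dist_spec <- function(family = c("normal", "lognormal", "weibull", "beta"), ...) {
  family <- match.arg(family)
  params <- list(...)
  expected <- dist_param_names(family)
  if (!setequal(names(params), expected)) {
    abort(paste0(
      "family '", family, "' needs parameters {",
      paste(expected, collapse = ", "), "}, got {",
      paste(names(params), collapse = ", "), "}"
    ), class = "varhet_parameter_error")
  }
  params <- params[expected]
  vals <- unlist(params)
  if (any(!is.finite(vals))) {
    abort("distribution parameters must be finite", class = "varhet_parameter_error")
  }
  positive <- switch(family,
    normal = "sd",
    lognormal = "sdlog",
    weibull = c("shape", "scale"),
    beta = c("shape1", "shape2")
  )
  bad <- positive[unlist(params[positive]) <= 0]
  if (length(bad) > 0) {
    abort(paste0("parameter(s) ", paste(bad, collapse = ", "), " must be > 0"),
      class = "varhet_parameter_error"
    )
  }
  structure(list(family = family, params = params), class = "dist_spec")
}

dist_param_names <- function(family) {
  switch(family,
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    weibull = c("shape", "scale"),
    beta = c("shape1", "shape2")
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$family, "(",
    paste(names(x$params), signif(unlist(x$params), 5), sep = " = ", collapse = ", "),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.dist_spec <- function(x, ...) {
  paste0(x$family, "(", paste(signif(unlist(x$params), 5), collapse = ", "), ")")
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Effect size specification for two-group designs
#'
#' Describes how a comparison group differs from a baseline distribution: an
#' additive shift of the mean on the natural scale and a multiplicative
#' fold-change of the standard deviation. `effect_spec(0, 1)` is the identity
#' (the null); `variance_effect` multiplies the SD, so a value of 2 doubles
#' the spread on both the SD and (squared) the variance scale.
#'
#' @param mean_effect Additive shift of the natural-scale mean.
#' @param variance_effect Multiplicative fold-change of the standard
#'   deviation; must be > 0.
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(mean_effect = 1, variance_effect = 2)
#' @export
effect_spec <- function(mean_effect = 0, variance_effect = 1) {
  if (!is.finite(mean_effect) || !is.finite(variance_effect) || variance_effect <= 0) {
    abort("mean_effect must be finite and variance_effect > 0",
      class = "varhet_parameter_error"
    )
  }
  structure(list(mean_effect = mean_effect, variance_effect = variance_effect),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec> mean ", ifelse(x$mean_effect >= 0, "+", ""), x$mean_effect,
    ", sd x", x$variance_effect, "\n",
    sep = ""
  )
  invisible(x)
}

#' Closed-form moments of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return A one-row tibble with columns `mean`, `variance`, `skewness` and
#'   `kurtosis_excess`.
#' @examples
#' dist_moments(dist_spec("weibull", shape = 1, scale = 1)) # exponential
#' @export
dist_moments <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$params
  m <- switch(spec$family,
    normal = c(p$mean, p$sd^2, 0, 0),
    lognormal = {
      s2 <- p$sdlog^2
      ew <- exp(s2)
      mean <- exp(p$meanlog + s2 / 2)
      variance <- (ew - 1) * exp(2 * p$meanlog + s2)
      skew <- (ew + 2) * sqrt(ew - 1)
      kurt <- exp(4 * s2) + 2 * exp(3 * s2) + 3 * exp(2 * s2) - 6
      c(mean, variance, skew, kurt)
    },
    weibull = {
      g <- function(i) gamma(1 + i / p$shape)
      g1 <- g(1); g2 <- g(2); g3 <- g(3); g4 <- g(4)
      mean <- p$scale * g1
      variance <- p$scale^2 * (g2 - g1^2)
      sdv <- sqrt(variance)
      mu3 <- p$scale^3 * (g3 - 3 * g1 * g2 + 2 * g1^3)
      mu4 <- p$scale^4 * (g4 - 4 * g1 * g3 + 6 * g1^2 * g2 - 3 * g1^4)
      c(mean, variance, mu3 / sdv^3, mu4 / variance^2 - 3)
    },
    beta = {
      a <- p$shape1; b <- p$shape2
      mean <- a / (a + b)
      variance <- a * b / ((a + b)^2 * (a + b + 1))
      skew <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
      kurt <- 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
        (a * b * (a + b + 2) * (a + b + 3))
      c(mean, variance, skew, kurt)
    }
  )
  tibble::tibble(
    mean = m[1], variance = m[2], skewness = m[3], kurtosis_excess = m[4]
  )
}

dist_mean_sd <- function(spec) {
  mo <- dist_moments(spec)
  c(mean = mo$mean, sd = sqrt(mo$variance))
}

#' Draw a random sample from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the draw is reproducible.
#' @return A numeric vector of length `n` inside the family's support.
#' @examples
#' dist_sample(dist_spec("normal", mean = 0, sd = 1), 5, seed = 1)
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(is_dist_spec(spec))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("n must be a positive integer", class = "varhet_parameter_error")
  }
  p <- spec$params
  with_seed(seed, switch(spec$family,
    normal = rnorm(n, p$mean, p$sd),
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    weibull = rweibull(n, p$shape, p$scale),
    beta = rbeta(n, p$shape1, p$shape2)
  ))
}

dist_density <- function(spec, x, log = FALSE) {
  p <- spec$params
  switch(spec$family,
    normal = dnorm(x, p$mean, p$sd, log = log),
    lognormal = dlnorm(x, p$meanlog, p$sdlog, log = log),
    weibull = dweibull(x, p$shape, p$scale, log = log),
    beta = dbeta(x, p$shape1, p$shape2, log = log)
  )
}

#' Apply a mean/variance effect to a distribution
#'
#' Returns a member of the same family whose natural-scale mean is
#' `mean(spec) + mean_effect` and whose standard deviation is
#' `sd(spec) * variance_effect`. The normal family is reparameterised
#' directly; log-normal, Weibull and beta are moment-matched by solving the
#' family's mean/variance equations. Requests outside the family's feasible
#' set (e.g. a non-positive target mean for a Weibull, or a variance
#' exceeding `m(1-m)` for a beta) raise an infeasible-effect error rather
#' than clipping silently.
#'
#' @param spec A [dist_spec()].
#' @param effect An [effect_spec()].
#' @return A new [dist_spec()] of the same family.
#' @examples
#' apply_effect(dist_spec("normal", mean = 0, sd = 1), effect_spec(1, 2))
#' @export
apply_effect <- function(spec, effect) {
  stopifnot(is_dist_spec(spec), inherits(effect, "effect_spec"))
  ms <- dist_mean_sd(spec)
  m <- ms[["mean"]] + effect$mean_effect
  s <- ms[["sd"]] * effect$variance_effect
  spec_from_moments(spec$family, m, s)
}

# solve family parameters from a target (mean, sd); shared by apply_effect
spec_from_moments <- function(family, m, s) {
  infeasible <- function(msg) {
    abort(paste0("infeasible effect for family '", family, "': ", msg),
      class = "varhet_infeasible_effect_error"
    )
  }
  switch(family,
    normal = dist_spec("normal", mean = m, sd = s),
    lognormal = {
      if (m <= 0) infeasible("target mean must be positive")
      s2 <- log1p(s^2 / m^2)
      dist_spec("lognormal", meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    weibull = {
      if (m <= 0) infeasible("target mean must be positive")
      cv2 <- (s / m)^2
      # cv^2(k) = Gamma(1+2/k)/Gamma(1+1/k)^2 - 1 is strictly decreasing in k
      f <- function(k) expm1(lgamma(1 + 2 / k) - 2 * lgamma(1 + 1 / k)) - cv2
      lo <- 0.02; hi <- 500
      if (f(lo) < 0 || f(hi) > 0) infeasible("coefficient of variation out of range")
      k <- uniroot(f, c(lo, hi), tol = 1e-12)$root
      dist_spec("weibull", shape = k, scale = m / gamma(1 + 1 / k))
    },
    beta = {
      if (m <= 0 || m >= 1) infeasible("target mean must lie in (0, 1)")
      v <- s^2
      if (v >= m * (1 - m)) infeasible("target variance exceeds m(1-m)")
      t <- m * (1 - m) / v - 1
      dist_spec("beta", shape1 = m * t, shape2 = (1 - m) * t)
    }
  )
}

#' Maximum-likelihood fit of a single distribution
#'
#' Normal and log-normal fits are closed form; the Weibull shape solves the
#' profile-likelihood equation by safeguarded Newton iteration; the beta fit
#' runs Newton on the digamma score equations from a method-of-moments start.
#'
#' @param values Numeric vector (n >= 5) inside the family's support.
#' @param family Target family.
#' @return A [dist_spec()] with attributes `loglik` and `n`.
#' @examples
#' x <- dist_sample(dist_spec("weibull", shape = 2, scale = 3), 500, seed = 1)
#' fit_single(x, "weibull")
#' @export
fit_single <- function(values, family = c("normal", "lognormal", "weibull", "beta")) {
  family <- match.arg(family)
  values <- check_values(values, min_n = 5)
  check_support(values, family)
  if (stats::var(values) == 0) {
    abort("values are constant; no non-degenerate fit exists",
      class = "varhet_degenerate_error"
    )
  }
  n <- length(values)
  fit <- switch(family,
    normal = {
      m <- mean(values)
      s <- sqrt(mean((values - m)^2)) # MLE variance (n denominator)
      dist_spec("normal", mean = m, sd = s)
    },
    lognormal = {
      lx <- log(values)
      m <- mean(lx)
      s <- sqrt(mean((lx - m)^2))
      dist_spec("lognormal", meanlog = m, sdlog = s)
    },
    weibull = {
      res <- weibull_wmle_cpp(values, rep(1, n), shape_init = weibull_shape_start(values))
      if (!res$ok) {
        abort("Weibull fit did not converge", class = "varhet_convergence_error")
      }
      dist_spec("weibull", shape = res$shape, scale = res$scale)
    },
    beta = fit_beta_newton(values)
  )
  ll <- sum(dist_density(fit, values, log = TRUE))
  attr(fit, "loglik") <- ll
  attr(fit, "n") <- n
  fit
}

weibull_shape_start <- function(values) {
  s <- stats::sd(log(values))
  max(0.05, min(1.2 / s, 100))
}

fit_beta_newton <- function(values) {
  n <- length(values)
  m <- mean(values)
  v <- mean((values - m)^2)
  # method-of-moments start, guarded away from the boundary
  t0 <- max(m * (1 - m) / v - 1, 1e-3)
  th <- c(max(m * t0, 1e-3), max((1 - m) * t0, 1e-3))
  slx <- mean(log(values))
  sl1x <- mean(log1p(-values))
  for (i in 1:200) {
    a <- th[1]; b <- th[2]
    g <- c(
      digamma(a + b) - digamma(a) + slx,
      digamma(a + b) - digamma(b) + sl1x
    )
    tg <- trigamma(a + b)
    H <- matrix(c(tg - trigamma(a), tg, tg, tg - trigamma(b)), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new <- th - step
    # halve steps that leave the parameter space
    half <- 0
    while (any(new <= 0) && half < 50) {
      step <- step / 2
      new <- th - step
      half <- half + 1
    }
    if (any(new <= 0)) break
    if (max(abs(new - th) / (th + 1e-12)) < 1e-12) {
      th <- new
      break
    }
    th <- new
  }
  if (any(!is.finite(th)) || any(th <= 0)) {
    abort("beta fit did not converge", class = "varhet_convergence_error")
  }
  dist_spec("beta", shape1 = th[1], shape2 = th[2])
}

check_values <- function(values, min_n = 2) {
  if (!is.numeric(values)) abort("values must be numeric", class = "varhet_data_error")
  values <- values[!is.na(values)]
  if (length(values) < min_n) {
    abort(paste0("need at least ", min_n, " non-missing values"),
      class = "varhet_size_error"
    )
  }
  if (any(!is.finite(values))) {
    abort("values must be finite", class = "varhet_data_error")
  }
  values
}

check_support <- function(values, family) {
  ok <- switch(family,
    normal = TRUE,
    lognormal = all(values > 0),
    weibull = all(values > 0),
    beta = all(values > 0 & values < 1)
  )
  if (!isTRUE(ok)) {
    abort(paste0("values outside the support of family '", family, "'"),
      class = "varhet_support_error"
    )
  }
  invisible(TRUE)
}
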