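#' Fit a K-component mixture by expectation-maximisation
#'
#' Maximum-likelihood mixture fitting for the normal, log-normal and Weibull
#' families. The E-step computes Bayes responsibilities in log space; the
#' M-step is the weighted MLE per component (normal closed form; log-normal
#' fitted as a normal mixture on `log(x)`; the Weibull shape by safeguarded
#' Newton on the weighted profile-likelihood equation). Fitting stops when
#' the relative log-likelihood change falls below `tol` or after `max_iter`
#' iterations, and the best of `n_restarts` differently-initialised runs (by
#' log-likelihood) is returned. Components in the returned fit are sorted by
#' ascending natural-scale mean.
#'
#' Restart schedule: the first run uses the requested `init` (`"quantile"`
#' seeds component j from the j-th quantile block of the sorted data;
#' `"kmeans"` uses a k-means partition); later runs perturb by drawing random
#' data points as centres. A component collapsing (weight below 1e-4, or a
#' normal sd below `1e-6 * sd(x)`) invalidates that run; if every restart
#' collapses a degenerate-fit error is raised.
#'
#' @param values Numeric data vector, `n >= 5 * K`; positive for the
#'   log-normal and Weibull families.
#' @param family `"normal"`, `"lognormal"` or `"weibull"`.
#' @param K Number of components (>= 1).
#' @param init Initialisation of the first run.
#' @param n_restarts Number of initialisations (>= 1).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per run.
#' @param seed Optional integer seed driving the random restarts.
#' @return An object of class `mixture_fit` with elements `family`, `K`,
#'   `weights`, `components`, `log_likelihood`, `posteriors`, `n_iter`,
#'   `converged`, `ll_trace` and the data used.
#' @seealso [bootstrap_lrt()], [classify_modes()], [bic()]
#' @examples
#' spec <- mixture_spec(
#'   list(
#'     dist_spec("normal", mean = 0, sd = 1),
#'     dist_spec("normal", mean = 5, sd = 1)
#'   ),
#'   weights = c(0.5, 0.5)
#' )
#' x <- sample_mixture(spec, 300, seed = 1)$value
#' fit <- em_fit(x, "normal", K = 2, seed = 1)
#' tidy(fit)
#' @export
em_fit <- function(values, family = c("normal", "lognormal", "weibull"), K,
                   init = c("quantile", "kmeans"), n_restarts = 5,
                   tol = 1e-8, max_iter = 1000, seed = NULL) {
  family <- match.arg(family)
  init <- match.arg(init)
  values <- check_values(values, min_n = 5 * K)
  check_support(values, family)
  core <- em_core(values, family, K, init, n_restarts, tol, max_iter, seed)
  build_mixture_fit(values, family, core)
}

# fast path shared with bootstrap_lrt: returns raw parameters + loglik only.
# Multiple restarts use the short-EM strategy: every initialisation runs a
# capped number of iterations, and only the most promising run (by
# log-likelihood) is continued to full convergence.
em_core <- function(values, family, K, init = "quantile", n_restarts = 5,
                    tol = 1e-8, max_iter = 1000, seed = NULL) {
  x <- if (family == "lognormal") log(values) else values
  engine_family <- if (family == "weibull") "weibull" else "normal"
  n <- length(x)

  sd_x <- stats::sd(x)
  if (is.na(sd_x) || sd_x == 0) {
    abort("values are constant; mixture fit is degenerate",
      class = "varhet_degenerate_error"
    )
  }
  sd_floor <- 1e-6 * sd_x

  best <- if (K == 1) {
    em_single_component(x, engine_family, sd_floor)
  } else {
    em_multi_component(
      x, engine_family, K, init, n_restarts, tol, max_iter, seed, sd_floor
    )
  }
  if (is.null(best)) {
    abort("all EM restarts collapsed to a degenerate fit",
      class = "varhet_degenerate_fit_error"
    )
  }
  best$engine_family <- engine_family
  # map lognormal back: loglik transforms by the Jacobian of log(x)
  if (family == "lognormal") {
    jac <- sum(log(values))
    best$loglik <- best$loglik - jac
    best$trace <- best$trace - jac
  }
  best
}

em_single_component <- function(x, engine_family, sd_floor) {
  n <- length(x)
  if (engine_family == "normal") {
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s < sd_floor) return(NULL)
    ll <- sum(dnorm(x, m, s, log = TRUE))
    list(
      weights = 1, p1 = m, p2 = s, loglik = ll, n_iter = 1L,
      converged = TRUE, degenerate = FALSE, trace = ll
    )
  } else {
    res <- weibull_wmle_cpp(x, rep(1, n), shape_init = weibull_shape_start(x))
    if (!res$ok) return(NULL)
    ll <- sum(dweibull(x, res$shape, res$scale, log = TRUE))
    list(
      weights = 1, p1 = res$shape, p2 = res$scale, loglik = ll, n_iter = 1L,
      converged = TRUE, degenerate = FALSE, trace = ll
    )
  }
}

em_run <- function(x, engine_family, ini, tol, max_iter, sd_floor) {
  if (engine_family == "normal") {
    em_normal_cpp(x, ini$w, ini$p1, ini$p2, tol, max_iter, sd_floor)
  } else {
    em_weibull_cpp(x, ini$w, ini$p1, ini$p2, tol, max_iter)
  }
}

em_multi_component <- function(x, engine_family, K, init, n_restarts, tol,
                               max_iter, seed, sd_floor) {
  xs <- sort.int(x, method = "quick")
  inits <- lapply(seq_len(n_restarts), function(r) {
    em_init(xs, engine_family, K,
      method = if (r == 1) init else "random",
      seed = if (is.null(seed)) NULL else derive_seed(seed, r, stream = 7L),
      sd_floor = sd_floor
    )
  })
  if (n_restarts == 1) {
    res <- em_run(x, engine_family, inits[[1]], tol, max_iter, sd_floor)
    if (res$degenerate || !is.finite(res$loglik)) return(NULL)
    return(res)
  }
  # short runs for every initialisation
  shorts <- lapply(inits, function(ini) {
    res <- em_run(x, engine_family, ini, tol, min(25L, max_iter), sd_floor)
    if (res$degenerate || !is.finite(res$loglik)) NULL else res
  })
  lls <- vapply(shorts, function(s) if (is.null(s)) -Inf else s$loglik, numeric(1))
  for (j in order(lls, decreasing = TRUE)) {
    s <- shorts[[j]]
    if (is.null(s)) next
    if (s$converged) return(s)
    warm <- list(w = s$weights, p1 = s$p1, p2 = s$p2)
    res <- em_run(x, engine_family, warm, tol, max_iter, sd_floor)
    if (!res$degenerate && is.finite(res$loglik)) {
      res$n_iter <- res$n_iter + s$n_iter
      return(res)
    }
  }
  # every scheduled restart collapsed (EM drifting into the likelihood
  # singularity); draw a bounded reserve of fresh random initialisations
  for (r in n_restarts + seq_len(20)) {
    ini <- em_init(xs, engine_family, K,
      method = "random",
      seed = if (is.null(seed)) NULL else derive_seed(seed, r, stream = 7L),
      sd_floor = sd_floor
    )
    res <- em_run(x, engine_family, ini, tol, max_iter, sd_floor)
    if (!res$degenerate && is.finite(res$loglik)) {
      return(res)
    }
  }
  # no interior K-component optimum is reachable: fall back to K identical
  # components (the single-component MLE embedded in the K-component space).
  # Its likelihood is exactly the K=1 likelihood, so downstream LRTs see no
  # spurious evidence for extra components from singularity artefacts.
  single <- em_single_component(x, engine_family, sd_floor)
  if (is.null(single)) {
    return(NULL)
  }
  list(
    weights = rep(1 / K, K), p1 = rep(single$p1, K), p2 = rep(single$p2, K),
    loglik = single$loglik, n_iter = single$n_iter, converged = TRUE,
    degenerate = FALSE, boundary = TRUE, trace = single$trace
  )
}

em_init <- function(xs, engine_family, K, method, seed, sd_floor) {
  n <- length(xs)
  if (K == 1) {
    centers <- mean(xs)
    groups <- rep(1L, n)
  } else if (method == "quantile") {
    groups <- as.integer(cut(seq_len(n), breaks = K, labels = FALSE))
    centers <- vapply(seq_len(K), function(k) mean(xs[groups == k]), numeric(1))
  } else if (method == "kmeans") {
    km <- with_seed(seed, kmeans(xs, centers = K, nstart = 2))
    ord <- order(km$centers[, 1])
    groups <- match(km$cluster, ord)
    centers <- sort(km$centers[, 1])
  } else { # random data points as centres, nearest-centre partition
    centers <- sort(with_seed(seed, xs[sample.int(n, K)]))
    groups <- max.col(-abs(outer(xs, centers, "-")), ties.method = "first")
  }
  s_all <- max(stats::sd(xs), sd_floor)
  if (engine_family == "normal") {
    p1 <- centers
    p2 <- vapply(seq_len(K), function(k) {
      xk <- xs[groups == k]
      s <- if (length(xk) > 1) stats::sd(xk) else 0
      if (!is.finite(s) || s < sd_floor) s_all / max(K, 2) else s
    }, numeric(1))
  } else {
    # Weibull: shape from the log-scale spread of each block, scale from centre
    p1 <- vapply(seq_len(K), function(k) {
      xk <- xs[groups == k]
      if (length(xk) > 4) weibull_shape_start(xk) else 1.5
    }, numeric(1))
    centers <- pmax(centers, .Machine$double.eps)
    p2 <- centers / gamma(1 + 1 / p1)
  }
  w <- tabulate(groups, nbins = K) / n
  w <- pmax(w, 1e-3)
  list(w = w / sum(w), p1 = p1, p2 = p2)
}

build_mixture_fit <- function(values, family, core) {
  K <- length(core$weights)
  components <- lapply(seq_len(K), function(k) {
    switch(family,
      normal = dist_spec("normal", mean = core$p1[k], sd = core$p2[k]),
      lognormal = dist_spec("lognormal", meanlog = core$p1[k], sdlog = core$p2[k]),
      weibull = dist_spec("weibull", shape = core$p1[k], scale = core$p2[k])
    )
  })
  means <- vapply(components, function(s) dist_mean_sd(s)[["mean"]], numeric(1))
  ord <- order(means)
  components <- components[ord]
  weights <- core$weights[ord]

  # responsibilities at the final parameters
  n <- length(values)
  logd <- matrix(0, n, K)
  for (k in seq_len(K)) {
    logd[, k] <- log(weights[k]) + dist_density(components[[k]], values, log = TRUE)
  }
  mx <- apply(logd, 1, max)
  post <- exp(logd - mx)
  post <- post / rowSums(post)

  structure(
    list(
      family = family, K = K, weights = weights, components = components,
      log_likelihood = core$loglik, posteriors = post,
      n_iter = core$n_iter, converged = core$converged,
      ll_trace = core$trace, data = values
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", x$K, "-component ", x$family,
    ", logLik = ", format(x$log_likelihood, digits = 6),
    ", ", x$n_iter, " iterations",
    if (!x$converged) " (not converged)", "\n",
    sep = ""
  )
  for (k in seq_len(x$K)) {
    cat(
      "  w =", format(round(x$weights[k], 4), nsmall = 2), " ",
      format(x$components[[k]]), "\n"
    )
  }
  invisible(x)
}

#' Classify observations to their most probable mixture component
#'
#' Hard assignment by posterior mode. Components are in ascending-mean order,
#' and posterior ties resolve to the lower-mean component.
#'
#' @param fit A [em_fit()] result.
#' @return Integer vector of component labels.
#' @export
classify_modes <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  max.col(fit$posteriors, ties.method = "first")
}

#' Bayesian information criterion of a mixture fit
#'
#' `-2 logLik + p log(n)` with `p = (K - 1) + 2K` free parameters (weights
#' plus two parameters per component). Smaller is better.
#'
#' @param fit A [em_fit()] result.
#' @return A single number.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  p <- (fit$K - 1) + 2 * fit$K
  -2 * fit$log_likelihood + p * log(length(fit$data))
}

#' @export
tidy.mixture_fit <- function(x, ...) {
  pn <- dist_param_names(x$components[[1]]$family)
  rows <- lapply(seq_len(x$K), function(k) {
    ms <- dist_mean_sd(x$components[[k]])
    tibble::tibble(
      component = k,
      weight = x$weights[k],
      !!pn[1] := x$components[[k]]$params[[1]],
      !!pn[2] := x$components[[k]]$params[[2]],
      mean_natural = ms[["mean"]],
      sd_natural = ms[["sd"]]
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, K = x$K,
    log_likelihood = x$log_likelihood, bic = bic(x),
    n_iter = x$n_iter, converged = x$converged, n = length(x$data)
  )
}

#' @export
augment.mixture_fit <- function(x, ...) {
  out <- tibble::tibble(value = x$data, .component = classify_modes(x))
  post <- tibble::as_tibble(x$posteriors, .name_repair = function(nm) {
    paste0(".posterior_", seq_along(nm))
  })
  dplyr::bind_cols(out, post)
}

#' @export
autoplot.mixture_fit <- function(object, bins = 40, ...) {
  df <- tibble::tibble(value = object$data)
  grid <- seq(min(object$data), max(object$data), length.out = 400)
  dens <- lapply(seq_len(object$K), function(k) {
    tibble::tibble(
      value = grid,
      density = object$weights[k] * dist_density(object$components[[k]], grid),
      component = factor(k)
    )
  })
  dens <- dplyr::bind_rows(dens)
  total <- dplyr::summarise(
    dplyr::group_by(dens, .data$value),
    density = sum(.data$density), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component)
    ) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density), linewidth = 1) +
    ggplot2::labs(
      x = "value", y = "density",
      title = paste0(object$K, "-component ", object$family, " mixture")
    ) +
    ggplot2::theme_minimal()
}
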