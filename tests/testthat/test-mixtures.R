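test_that("a K=1 EM fit reduces exactly to the single-distribution MLE", {
  for (fam in c("normal", "lognormal", "weibull")) {
    x <- dist_sample(dist_spec("weibull", shape = 2, scale = 3), 400, seed = 3)
    fit1 <- em_fit(x, fam, K = 1, seed = 1)
    single <- fit_single(x, fam)
    expect_equal(fit1$log_likelihood, attr(single, "loglik"), tolerance = 1e-8)
    expect_equal(
      unlist(fit1$components[[1]]$params),
      unlist(single$params),
      tolerance = 1e-6
    )
    expect_true(all(fit1$posteriors == 1))
  }
})

test_that("EM recovers a well-separated two-component Gaussian mixture", {
  spec <- bimodal_normal_spec(delta = 5, w = 0.5)
  x <- sample_mixture(spec, 1000, seed = 101)$value
  fit <- em_fit(x, "normal", K = 2, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$components[[1]]$params$mean - 0), 0.15)
  expect_lt(abs(fit$components[[2]]$params$mean - 5), 0.15)
  expect_lt(max(abs(fit$weights - 0.5)), 0.05)
  # posteriors are a proper responsibility matrix
  expect_equal(rowSums(fit$posteriors), rep(1, 1000), tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
})

test_that("EM log-likelihood trace is nondecreasing on every fit", {
  set.seed(7)
  for (r in 1:20) {
    fam <- sample(c("normal", "lognormal", "weibull"), 1)
    x <- switch(fam,
      normal = c(rnorm(60), rnorm(60, sample(1:5, 1))),
      lognormal = exp(rnorm(120, 0, 0.7)),
      weibull = rweibull(120, runif(1, 0.8, 3), 2)
    )
    fit <- em_fit(x, fam, K = 2, seed = r)
    expect_true(all(diff(fit$ll_trace) >= -1e-8 * (abs(fit$ll_trace[-1]) + 1)),
      info = paste(fam, r)
    )
  }
})

test_that("parameter recovery error decreases from n = 200 to n = 2000", {
  spec <- bimodal_normal_spec(delta = 5, w = 0.5)
  med_err <- vapply(c(200, 2000), function(n) {
    errs <- vapply(1:50, function(s) {
      x <- sample_mixture(spec, n, seed = derive_seed(77, s, stream = n))$value
      fit <- em_fit(x, "normal", K = 2, seed = s)
      max(
        abs(fit$components[[1]]$params$mean - 0),
        abs(fit$components[[2]]$params$mean - 5),
        abs(fit$weights[1] - 0.5)
      )
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
})

test_that("lognormal mixture machinery equals Gaussian machinery on logs", {
  spec <- bimodal_normal_spec(delta = 3, w = 0.4)
  z <- sample_mixture(spec, 300, seed = 55)$value
  x <- exp(z)
  fit_ln <- em_fit(x, "lognormal", K = 2, seed = 9)
  fit_n <- em_fit(z, "normal", K = 2, seed = 9)
  expect_equal(fit_ln$weights, fit_n$weights, tolerance = 1e-6)
  expect_equal(
    vapply(fit_ln$components, function(s) s$params$meanlog, numeric(1)),
    vapply(fit_n$components, function(s) s$params$mean, numeric(1)),
    tolerance = 1e-6
  )
  # log-likelihoods differ exactly by the Jacobian sum(log x)
  expect_equal(fit_ln$log_likelihood, fit_n$log_likelihood - sum(log(x)),
    tolerance = 1e-6
  )
  # end-to-end: bootstrap LRT p-values agree at matched seeds
  b_ln <- bootstrap_lrt(x, "lognormal", n_boot = 60, seed = 13)
  b_n <- bootstrap_lrt(z, "normal", n_boot = 60, seed = 13)
  expect_equal(b_ln$p_value, b_n$p_value)
  expect_equal(b_ln$lrt_statistic, b_n$lrt_statistic, tolerance = 1e-6)
})

test_that("Weibull M-step solves the weighted-likelihood score equation", {
  set.seed(17)
  x <- c(rweibull(150, 1.5, 1), rweibull(150, 4, 6))
  # the M-step solver itself: profile score at the returned shape vanishes
  # for arbitrary responsibility weights
  for (rep in 1:10) {
    r <- runif(length(x))
    res <- varhet:::weibull_wmle_cpp(x, r, 1.0)
    expect_true(res$ok)
    g <- sum(r * x^res$shape * log(x)) / sum(r * x^res$shape) - 1 / res$shape -
      sum(r * log(x)) / sum(r)
    expect_lt(abs(g), 1e-8)
    # and the scale is the weighted closed form given the shape
    expect_equal(res$scale, (sum(r * x^res$shape) / sum(r))^(1 / res$shape),
      tolerance = 1e-10
    )
  }
  # at EM convergence the fixed point approximately satisfies the same score
  fit <- em_fit(x, "weibull", K = 2, tol = 1e-12, max_iter = 5000, seed = 3)
  post <- fit$posteriors
  for (k in 1:2) {
    r <- post[, k]
    shape <- fit$components[[k]]$params$shape
    g <- sum(r * x^shape * log(x)) / sum(r * x^shape) - 1 / shape -
      sum(r * log(x)) / sum(r)
    expect_lt(abs(g), 1e-5)
  }
})

test_that("permuting the initial component order leaves the sorted fit unchanged", {
  set.seed(23)
  x <- c(rnorm(80), rnorm(80, 4))
  ini <- list(w = c(0.4, 0.6), p1 = c(0.2, 3.5), p2 = c(1.2, 1.2))
  ini_perm <- list(w = rev(ini$w), p1 = rev(ini$p1), p2 = rev(ini$p2))
  r1 <- varhet:::em_run(x, "normal", ini, 1e-8, 1000, 1e-6 * sd(x))
  r2 <- varhet:::em_run(x, "normal", ini_perm, 1e-8, 1000, 1e-6 * sd(x))
  expect_equal(r1$loglik, r2$loglik, tolerance = 1e-6)
  expect_equal(sort(r1$p1), sort(r2$p1), tolerance = 1e-6)
  expect_equal(sort(r1$weights), sort(r2$weights), tolerance = 1e-6)
  # and public fits always come back sorted by component mean
  fit <- em_fit(x, "normal", K = 2, seed = 2)
  means <- vapply(fit$components, function(s) s$params$mean, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("Gaussian EM agrees with an independent EM implementation", {
  withr::local_package("mclust") # Mclust needs its namespace attached
  set.seed(29)
  x <- c(rnorm(200, 0, 1), rnorm(200, 4, 1.5))
  ours <- em_fit(x, "normal", K = 2, n_restarts = 8, seed = 5)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$log_likelihood, ref$loglik, tolerance = 1e-4)
  expect_equal(
    vapply(ours$components, function(s) s$params$mean, numeric(1)),
    unname(ref$parameters$mean),
    tolerance = 0.02
  )
})

test_that("classify_modes uses the posterior mode with ties to the lower mean", {
  spec <- bimodal_normal_spec(delta = 4, w = 0.5)
  draw <- sample_mixture(spec, 1000, seed = 61)
  fit <- em_fit(draw$value, "normal", K = 2, seed = 1)
  labels <- classify_modes(fit)
  expect_gte(mean(labels == draw$component), 0.98)
  # K = 1: everything in one class
  fit1 <- em_fit(draw$value, "normal", K = 1)
  expect_true(all(classify_modes(fit1) == 1))
  # exact tie goes to component 1 (lower mean)
  fit_tie <- fit
  fit_tie$posteriors <- matrix(0.5, 2, 2)
  expect_equal(classify_modes(fit_tie), c(1L, 1L))
})

test_that("BIC prefers two components on strongly bimodal data and counts parameters", {
  x <- sample_mixture(bimodal_normal_spec(delta = 5), 500, seed = 71)$value
  f1 <- em_fit(x, "normal", K = 1)
  f2 <- em_fit(x, "normal", K = 2, seed = 1)
  expect_lt(bic(f2), bic(f1))
  # hand parameter count: K=1 -> 2 params, K=2 -> 5 params
  expect_equal(bic(f1), -2 * f1$log_likelihood + 2 * log(500))
  expect_equal(bic(f2), -2 * f2$log_likelihood + 5 * log(500))
  expect_equal(bic(f1), bic(f1)) # deterministic on a fixed fit
})

test_that("bootstrap LRT detects a 4-sigma mixture and respects the add-one rule", {
  x <- sample_mixture(bimodal_normal_spec(delta = 4), 100, seed = 81)$value
  res <- bootstrap_lrt(x, "normal", n_boot = 99, seed = 4)
  expect_lt(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / 100)
  expect_gte(res$lrt_statistic, 0)
  expect_equal(res$n_boot, 99)
  # observed statistic below every bootstrap statistic gives p = 1
  fake <- res
  expect_equal((1 + sum(res$boot_stats >= 0)) / (res$n_boot + 1), 1)
  # tidy output contract
  td <- tidy(res)
  expect_named(td, c("method", "statistic", "p_value", "n_resamples", "seed"))
  expect_equal(td$method, "mix_lrt_normal")
})

test_that("degenerate inputs raise classified errors", {
  expect_error(em_fit(rep(2, 50), "normal", K = 2, seed = 1),
    class = "varhet_degenerate_error"
  )
  expect_error(em_fit(c(-1, rnorm(50)), "weibull", K = 2, seed = 1),
    class = "varhet_support_error"
  )
  expect_error(em_fit(rnorm(8), "normal", K = 2, seed = 1),
    class = "varhet_size_error"
  )
  expect_error(bootstrap_lrt(rnorm(100), "normal", K0 = 2, K1 = 2),
    class = "varhet_parameter_error"
  )
})
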