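test_that("closed-form moments match numerical integration for every family", {
  specs <- list(
    dist_spec("normal", mean = -1.3, sd = 2.2),
    dist_spec("lognormal", meanlog = 0.4, sdlog = 0.6),
    dist_spec("weibull", shape = 1, scale = 1), # exponential
    dist_spec("weibull", shape = 2.7, scale = 3.1),
    dist_spec("beta", shape1 = 2, shape2 = 5),
    dist_spec("beta", shape1 = 3, shape2 = 3)
  )
  for (spec in specs) {
    got <- unlist(dist_moments(spec))
    want <- moments_numeric(spec)
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # spot values: gaussian shape moments, exponential skewness, symmetric beta
  expect_equal(unlist(dist_moments(normal01())), c(0, 1, 0, 0), ignore_attr = TRUE)
  expo <- dist_moments(dist_spec("weibull", shape = 1, scale = 1))
  expect_equal(expo$mean, 1, tolerance = 1e-12)
  expect_equal(expo$variance, 1, tolerance = 1e-12)
  expect_equal(expo$skewness, 2, tolerance = 1e-10)
  expect_equal(dist_moments(dist_spec("beta", shape1 = 4, shape2 = 4))$skewness, 0)
})

test_that("sampling respects support, seed reproducibility and the LLN", {
  x <- dist_sample(normal01(), 1e5, seed = 11)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(sd(x) - 1), 0.02)
  w <- dist_sample(dist_spec("weibull", shape = 1, scale = 2), 1e5, seed = 12)
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 2), 0.03)
  b <- dist_sample(dist_spec("beta", shape1 = 2, shape2 = 2), 1e4, seed = 13)
  expect_true(all(b > 0 & b < 1))

  expect_identical(
    dist_sample(normal01(), 50, seed = 5),
    dist_sample(normal01(), 50, seed = 5)
  )
  # different seeds give same distribution (KS on large samples)
  x1 <- dist_sample(normal01(), 1e4, seed = 1)
  x2 <- dist_sample(normal01(), 1e4, seed = 2)
  expect_gt(suppressWarnings(ks.test(x1, x2))$p.value, 0.001)
})

test_that("invalid parameters are rejected", {
  expect_error(dist_spec("normal", mean = 5, sd = 0), class = "varhet_parameter_error")
  expect_error(dist_spec("weibull", shape = -1, scale = 2), class = "varhet_parameter_error")
  expect_error(dist_spec("beta", shape1 = 0, shape2 = 1), class = "varhet_parameter_error")
  expect_error(dist_spec("normal", mu = 0, sd = 1), class = "varhet_parameter_error")
  expect_error(effect_spec(0, 0), class = "varhet_parameter_error")
  expect_error(dist_sample(normal01(), 0), class = "varhet_parameter_error")
})

test_that("apply_effect hits the requested mean and sd exactly when feasible", {
  specs <- list(
    dist_spec("normal", mean = 2, sd = 3),
    dist_spec("lognormal", meanlog = 0, sdlog = 0.5),
    dist_spec("weibull", shape = 2, scale = 1),
    dist_spec("beta", shape1 = 2, shape2 = 6)
  )
  effects <- list(
    effect_spec(0, 1), # identity
    effect_spec(0, 1.5),
    effect_spec(0.1, 2),
    effect_spec(-0.05, 0.7)
  )
  for (spec in specs) {
    base <- dist_moments(spec)
    for (eff in effects) {
      target_mean <- base$mean + eff$mean_effect
      target_sd <- sqrt(base$variance) * eff$variance_effect
      feasible <- switch(spec$family,
        normal = TRUE,
        lognormal = target_mean > 0,
        weibull = target_mean > 0,
        beta = target_mean > 0 && target_mean < 1 &&
          target_sd^2 < target_mean * (1 - target_mean)
      )
      if (!feasible) next
      out <- apply_effect(spec, eff)
      expect_s3_class(out, "dist_spec")
      expect_identical(out$family, spec$family)
      got <- dist_moments(out)
      expect_equal(got$mean, target_mean, tolerance = 1e-6)
      expect_equal(sqrt(got$variance), target_sd, tolerance = 1e-6)
    }
  }
  # direct normal case
  out <- apply_effect(normal01(), effect_spec(1, 2))
  expect_equal(out$params$mean, 1)
  expect_equal(out$params$sd, 2)
  # weibull sd scaling against the closed-form Gamma-moment formulas
  w <- dist_spec("weibull", shape = 2, scale = 1)
  sd_w <- sqrt(dist_moments(w)$variance)
  out <- apply_effect(w, effect_spec(0, 1.5))
  expect_equal(sqrt(dist_moments(out)$variance), 1.5 * sd_w, tolerance = 1e-6)
})

test_that("infeasible effects error instead of clipping", {
  expect_error(
    apply_effect(dist_spec("weibull", shape = 2, scale = 1), effect_spec(-5, 1)),
    class = "varhet_infeasible_effect_error"
  )
  expect_error(
    apply_effect(dist_spec("beta", shape1 = 2, shape2 = 2), effect_spec(0, 3)),
    class = "varhet_infeasible_effect_error"
  )
  expect_error(
    apply_effect(dist_spec("lognormal", meanlog = 0, sdlog = 1), effect_spec(-10, 1)),
    class = "varhet_infeasible_effect_error"
  )
})

test_that("fit_single recovers parameters and rejects bad input", {
  x <- dist_sample(dist_spec("weibull", shape = 2, scale = 3), 5000, seed = 21)
  fit <- fit_single(x, "weibull")
  expect_lt(abs(fit$params$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$params$scale - 3) / 3, 0.05)

  b <- dist_sample(dist_spec("beta", shape1 = 2, shape2 = 5), 5000, seed = 22)
  fitb <- fit_single(b, "beta")
  expect_lt(abs(fitb$params$shape1 - 2) / 2, 0.1)
  expect_lt(abs(fitb$params$shape2 - 5) / 5, 0.1)

  expect_error(fit_single(rep(1, 10), "normal"), class = "varhet_degenerate_error")
  expect_error(fit_single(c(-1, 1, 2, 3, 4), "lognormal"), class = "varhet_support_error")
  expect_error(fit_single(c(0.2, 0.4, 1.2, 0.3, 0.5), "beta"), class = "varhet_support_error")
  expect_error(fit_single(rnorm(3), "normal"), class = "varhet_size_error")
})

test_that("fit_single matches an independent ML fitter and the log-transform identity", {
  set.seed(31)
  x <- rweibull(2000, 1.7, 2.5)
  ours <- fit_single(x, "weibull")
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(ours$params$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(ours$params$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
  # our Newton solution should be at least as good as the optim-based fit
  expect_gte(attr(ours, "loglik"), ref$loglik - 1e-6)

  y <- rbeta(2000, 2.2, 3.3)
  ours_b <- fit_single(y, "beta")
  ref_b <- fitdistrplus::fitdist(y, "beta")
  expect_equal(ours_b$params$shape1, unname(ref_b$estimate["shape1"]), tolerance = 1e-3)
  expect_equal(ours_b$params$shape2, unname(ref_b$estimate["shape2"]), tolerance = 1e-3)

  z <- rlnorm(500, 1, 0.5)
  ln <- fit_single(z, "lognormal")
  nm <- fit_single(log(z), "normal")
  expect_equal(ln$params$meanlog, nm$params$mean, tolerance = 1e-12)
  expect_equal(ln$params$sdlog, nm$params$sd, tolerance = 1e-12)
})

test_that("fit_single is consistent: error shrinks with n for every family", {
  families <- list(
    list(spec = dist_spec("normal", mean = 1, sd = 2), family = "normal"),
    list(spec = dist_spec("lognormal", meanlog = 0.3, sdlog = 0.5), family = "lognormal"),
    list(spec = dist_spec("weibull", shape = 2, scale = 3), family = "weibull"),
    list(spec = dist_spec("beta", shape1 = 2, shape2 = 4), family = "beta")
  )
  ns <- c(200, 2000, 20000)
  for (fam in families) {
    truth <- unlist(fam$spec$params)
    med_err <- vapply(ns, function(n) {
      errs <- vapply(1:50, function(s) {
        x <- dist_sample(fam$spec, n, seed = derive_seed(1000, s, stream = n))
        fit <- fit_single(x, fam$family)
        max(abs(unlist(fit$params) - truth) / abs(truth))
      }, numeric(1))
      median(errs)
    }, numeric(1))
    expect_true(all(diff(med_err) < 0), info = fam$family)
  }
})

test_that("mixture_spec validates and canonicalises component order", {
  comps <- list(
    dist_spec("normal", mean = 5, sd = 1),
    dist_spec("normal", mean = 0, sd = 1)
  )
  spec <- mixture_spec(comps, weights = c(0.7, 0.3))
  expect_equal(spec$components[[1]]$params$mean, 0) # sorted ascending
  expect_equal(spec$weights, c(0.3, 0.7))
  expect_error(mixture_spec(list()), class = "varhet_spec_error")
  expect_error(mixture_spec(comps, weights = c(0.5, 0.4)), class = "varhet_spec_error")
  expect_error(
    mixture_spec(list(comps[[1]], dist_spec("weibull", shape = 1, scale = 1))),
    class = "varhet_spec_error"
  )
})

test_that("sample_mixture label frequencies and moments match the spec", {
  spec <- bimodal_normal_spec(delta = 5, w = 0.5)
  draw <- sample_mixture(spec, 1e4, seed = 41)
  expect_lt(abs(mean(draw$component == 2) - 0.5), 0.015)

  spec37 <- bimodal_normal_spec(delta = 5, w = 0.3)
  draw37 <- sample_mixture(spec37, 1e4, seed = 42)
  mix_mean <- 0.3 * 0 + 0.7 * 5
  se <- varhet:::mixture_mean_sd(spec37)[["sd"]] / sqrt(1e4)
  expect_lt(abs(mean(draw37$value) - mix_mean), 3 * se)

  # degenerate single-component mixture: reproducible, same distribution as
  # plain sampling
  single <- mixture_spec(list(normal01()), weights = 1)
  expect_identical(
    sample_mixture(single, 100, seed = 7),
    sample_mixture(single, 100, seed = 7)
  )
  d1 <- sample_mixture(single, 5000, seed = 8)$value
  d2 <- dist_sample(normal01(), 5000, seed = 9)
  expect_gt(suppressWarnings(ks.test(d1, d2))$p.value, 0.001)
})
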