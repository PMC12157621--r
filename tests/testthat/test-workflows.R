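test_that("eda_summary recovers known moment geometry", {
  z <- dist_sample(normal01(), 1e4, seed = 51)
  s <- eda_summary(z, n_boot = 0)
  expect_lt(abs(s$cf_x), 0.01)
  expect_lt(abs(s$cf_y - 3), 0.15)
  expect_null(attr(s, "boot"))

  u <- dist_sample(dist_spec("beta", shape1 = 1, shape2 = 1), 1e4, seed = 52)
  su <- eda_summary(u, n_boot = 25, seed = 1)
  expect_lt(abs(su$cf_y - 1.8), 0.1)
  expect_equal(nrow(attr(su, "boot")), 25)

  expect_error(eda_summary(rep(1, 10)), class = "varhet_degenerate_error")
  p <- plot_cullen_frey(su)
  expect_s3_class(p, "ggplot")
})

test_that("compute_deltas follows the higher-minus-lower orientation", {
  expr <- matrix(c(2.0, 3.5, 1.0, 4.0), nrow = 2, byrow = TRUE,
    dimnames = list(c("gA", "gB"), c("s_lean", "s_heavy"))
  )
  meta <- data.frame(
    sample = c("s_lean", "s_heavy"), pair = "p1", covariate = c(21, 30)
  )
  d <- compute_deltas(expr, meta)
  expect_equal(d$p1, c(3.5 - 2.0, 4.0 - 1.0)) # heavy minus lean
  # swapping the covariates flips every sign
  meta2 <- meta
  meta2$covariate <- rev(meta2$covariate)
  d2 <- compute_deltas(expr, meta2)
  expect_equal(d2$p1, -d$p1)
})

test_that("compute_deltas preserves shape, flags ties, rejects broken pairs", {
  set.seed(53)
  expr <- matrix(rnorm(7 * 6), 7, 6,
    dimnames = list(paste0("g", 1:7), paste0("s", 1:6))
  )
  meta <- data.frame(
    sample = paste0("s", 1:6),
    pair = rep(c("p1", "p2", "p3"), each = 2),
    covariate = c(25, 30, 28, 28, 31, 22)
  )
  expect_warning(d <- compute_deltas(expr, meta), "tied")
  expect_equal(dim(varhet:::delta_values(d)), c(7, 3))
  expect_equal(d$feature, paste0("g", 1:7))
  pairs <- attr(d, "pairs")
  expect_true(pairs$tied[pairs$pair == "p2"])
  # tied pair: declared order wins (s3 treated as higher)
  expect_equal(d$p2, unname(expr[, "s3"] - expr[, "s4"]))

  expect_error(
    compute_deltas(expr, meta[-1, ]),
    class = "varhet_pair_error"
  )
  expect_error(
    compute_deltas(expr, transform(meta, sample = paste0("x", 1:6))),
    class = "varhet_pair_error"
  )
})

test_that("top_variable_features ranks by delta SD with stable ties", {
  set.seed(54)
  mat <- rbind(
    constant = rep(0.5, 12),
    noisy = rnorm(12, 0, 5),
    mild = rnorm(12, 0, 1)
  )
  colnames(mat) <- paste0("s", 1:12)
  meta <- data.frame(
    sample = paste0("s", 1:12),
    pair = rep(paste0("p", 1:6), each = 2),
    covariate = rep(c(1, 2), 6)
  )
  d <- compute_deltas(mat, meta)
  top2 <- top_variable_features(d, 2)
  expect_false("constant" %in% top2$feature) # zero-SD feature ranks last
  expect_true("noisy" %in% top2$feature)
  all3 <- top_variable_features(d, 3)
  expect_equal(all3$feature, d$feature) # k = n_features is the identity
  expect_error(top_variable_features(d, 10), class = "varhet_parameter_error")
})

test_that("bh_adjust reproduces the hand step-up and matches p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(55)
  p <- runif(40)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), class = "varhet_parameter_error")
})

test_that("mode_group_association matches hand chi-square values", {
  # diagonal 2x2 table [[10,0],[0,10]]: chi-square = n (ad-bc)^2 / products = 20
  res <- suppressWarnings(mode_group_association(
    rep(1:2, each = 10), rep(c("x", "y"), each = 10)
  ))
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  # perfectly proportional table: statistic 0
  res0 <- mode_group_association(
    rep(c(1, 2), times = c(20, 20)),
    rep(c("x", "y", "x", "y"), times = c(10, 10, 10, 10))
  )
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_warning(
    mode_group_association(
      factor(rep(1:2, each = 10), levels = 1:3),
      rep(c("x", "y"), 10)
    ),
    "zero marginal"
  )
  expect_error(mode_group_association(rep(1, 10), rep(c("x", "y"), 5)),
    class = "varhet_design_error"
  )
  # null calibration: p-values roughly uniform
  ps <- vapply(1:200, function(s) {
    set.seed(derive_seed(57, s))
    suppressWarnings(mode_group_association(
      sample(1:2, 40, replace = TRUE),
      sample(c("x", "y"), 40, replace = TRUE)
    )$p_value)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("the twin screen finds planted bimodal features and applies its filters", {
  # note the p-value granularity: with B bootstraps the smallest achievable
  # adjusted p is (1/(B+1)) * n_features / n_planted, so B must comfortably
  # exceed n_features / (fdr * n_planted)
  fx <- generate_fixture("twin_matrix",
    dir = withr::local_tempdir(),
    params = list(
      n_features = 40, n_bimodal = 10, n_pairs = 60, separation = 5,
      minority_range = c(0.2, 0.5)
    ),
    seed = 61
  )
  res <- screen_bimodal_features(fx$deltas,
    n_boot = 200, seed = 62,
    min_mode_prop = 0.10
  )
  truth <- fx$manifest$bimodal
  recall <- sum(res$pass & truth) / sum(truth)
  expect_gte(recall, 0.8)
  fdp <- if (sum(res$pass) > 0) sum(res$pass & !truth) / sum(res$pass) else 0
  expect_lte(fdp, 0.2)
  expect_true(all(res$p_adjusted >= res$p_value, na.rm = TRUE))
  expect_true(all(!res$pass[which(res$minority_prop < 0.10)]))
  expect_true(all(res$reason[res$pass] %in% NA_character_))
})

test_that("min-mode filtering excludes significant but outlier-driven features", {
  # one feature whose 'minority mode' is 4% of samples, far displaced
  set.seed(63)
  n_pairs <- 50
  mat <- rbind(
    outlier_gene = c(rnorm(48, 0, 0.5), 10, 10.5),
    clean_gene = c(rnorm(25, 0, 0.5), rnorm(25, 5, 0.5))
  )
  colnames(mat) <- paste0("s", 1:n_pairs)
  d <- tibble::tibble(feature = rownames(mat)) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
  class(d) <- c("delta_matrix", class(d))
  res <- screen_bimodal_features(d, n_boot = 80, seed = 64)
  out_row <- res[res$feature == "outlier_gene", ]
  clean_row <- res[res$feature == "clean_gene", ]
  expect_false(out_row$pass)
  expect_equal(out_row$reason, "min_mode")
  expect_lt(out_row$minority_prop, 0.10)
  expect_true(clean_row$pass)
})

test_that("fixture generation is deterministic and labelled correctly", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- generate_fixture("twin_matrix",
    dir = dir1,
    params = list(n_features = 30, n_bimodal = 6, n_pairs = 20), seed = 5
  )
  f2 <- generate_fixture("twin_matrix",
    dir = dir2,
    params = list(n_features = 30, n_bimodal = 6, n_pairs = 20), seed = 5
  )
  expect_identical(readLines(f1$paths[1]), readLines(f2$paths[1]))
  expect_identical(readLines(f1$paths[2]), readLines(f2$paths[2]))
  expect_equal(sum(f1$manifest$bimodal), 6)

  cohort <- generate_fixture("bimodal_cohort",
    dir = dir1,
    params = list(
      n = 4000,
      spec = bimodal_normal_spec(delta = 4, w = 0.28)
    ), seed = 6
  )
  prop2 <- mean(cohort$data$component == 2)
  expect_lt(abs(prop2 - 0.72), 3 * sqrt(0.28 * 0.72 / 4000) + 1e-9)

  tg <- generate_fixture("two_group_vh", dir = dir1, seed = 7)
  expect_true(file.exists(tg$paths))
  expect_named(tg$data, c("group", "value"))
})

test_that("screen results are reproducible under a fixed seed", {
  fx <- generate_fixture("twin_matrix",
    dir = withr::local_tempdir(),
    params = list(n_features = 10, n_bimodal = 2, n_pairs = 30), seed = 71
  )
  r1 <- screen_bimodal_features(fx$deltas, n_boot = 30, seed = 72)
  r2 <- screen_bimodal_features(fx$deltas, n_boot = 30, seed = 72)
  expect_identical(r1, r2)
})
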