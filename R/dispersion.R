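#' Validate a grouped sample data frame
#'
#' Checks the `group`/`value` contract used by every two-group test: matching
#' lengths, at least two observations per group, and no missing values (rows
#' with missing entries are dropped with a message).
#'
#' @param data A data frame with columns `group` and `value`.
#' @param min_per_group Minimum observations required in each group.
#' @return A tibble with columns `group` (factor) and `value` (numeric).
#' @export
as_sample_set <- function(data, min_per_group = 2) {
  if (!is.data.frame(data) || !all(c("group", "value") %in% names(data))) {
    abort("data must contain columns 'group' and 'value'",
      class = "varhet_input_contract_error"
    )
  }
  out <- tibble::tibble(
    group = factor(data$group),
    value = as.numeric(data$value)
  )
  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    inform(paste0("dropped ", sum(!keep), " row(s) with missing values"))
    out <- out[keep, ]
  }
  out$group <- droplevels(out$group)
  counts <- table(out$group)
  if (length(counts) < 2 || any(counts < min_per_group)) {
    abort(paste0("need >= 2 groups with >= ", min_per_group, " observations each"),
      class = "varhet_design_error"
    )
  }
  out
}

#' Read a group/value table from CSV or TSV
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return A validated tibble (see [as_sample_set()]).
#' @export
read_sample_set <- function(path) {
  df <- read_table_auto(path)
  if (!all(c("group", "value") %in% names(df))) {
    abort(paste0(
      "input table must have columns 'group' and 'value'; found: ",
      paste(names(df), collapse = ", ")
    ), class = "varhet_input_contract_error")
  }
  as_sample_set(df)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "varhet_input_contract_error")
  }
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

two_groups <- function(data) {
  data <- as_sample_set(data)
  if (nlevels(data$group) != 2) {
    abort("this test requires exactly 2 groups", class = "varhet_design_error")
  }
  split(data$value, data$group)
}

# uniform one-row result for every hypothesis test in the package
new_test_result <- function(method, statistic, p_value, n_resamples = NA_integer_,
                            seed = NA_integer_, extras = NULL) {
  out <- tibble::tibble(
    method = method,
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    n_resamples = as.integer(n_resamples),
    seed = as.integer(seed %||% NA_integer_)
  )
  attr(out, "extras") <- extras
  class(out) <- c("vh_test", class(out))
  out
}

#' @export
tidy.vh_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Gini mean difference
#'
#' The mean absolute difference over all unordered pairs,
#' `GMD = 2 / (n (n - 1)) * sum_{i<j} |x_i - x_j|`, a robust dispersion
#' measure. Computed in `O(n log n)` through the sorted-order identity
#' `GMD = 2 / (n (n - 1)) * sum_i (2i - n - 1) x_(i)`.
#'
#' @param values Numeric vector, `n >= 2`.
#' @return A non-negative scalar.
#' @examples
#' gini_mean_difference(c(1, 2, 3)) # 4/3
#' @export
gini_mean_difference <- function(values) {
  values <- check_values(values, min_n = 2)
  gini_cpp(values)
}

#' Median absolute deviation
#'
#' `median(|x - median(x)|)`, optionally scaled by 1.4826 so the statistic
#' estimates the SD under normality. The scaling constant cancels inside the
#' permutation-test ratio statistic, so the unscaled version is the default.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param scaled Multiply by 1.4826?
#' @return A non-negative scalar.
#' @examples
#' median_abs_deviation(c(1, 2, 3, 4, 5)) # 1
#' @export
median_abs_deviation <- function(values, scaled = FALSE) {
  values <- check_values(values, min_n = 2)
  stats::mad(values, constant = if (scaled) 1.4826 else 1)
}

dispersion_metric <- function(metric) {
  switch(metric,
    sd = stats::sd,
    mad = mad_cpp, # = stats::mad(x, constant = 1); C++ for permutation loops
    gini = gini_cpp
  )
}

#' Permutation test for a dispersion difference between two groups
#'
#' The observed statistic is `T = |log(D1 / D2)|`, where `D_g` is the chosen
#' dispersion metric (SD, unscaled MAD, or Gini mean difference) in group g
#' — symmetric in the group labels and free of the measurement scale. Group
#' labels are permuted `n_perm` times and the p-value uses the add-one rule
#' `p = (1 + #{T* >= T}) / (n_perm + 1)`, so it is never exactly zero.
#'
#' A group with zero dispersion (while the other is positive) is mapped to
#' the smallest representable positive value with a warning, preserving the
#' extremeness ordering; two zero-dispersion groups are degenerate.
#'
#' @param data Data frame with columns `group` (exactly 2 levels) and `value`.
#' @param metric `"sd"`, `"mad"` or `"gini"`.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return A one-row tibble of class `vh_test` (method, statistic, p_value,
#'   n_resamples, seed), with the per-group dispersions in
#'   `attr(, "extras")`.
#' @examples
#' d <- tibble::tibble(
#'   group = rep(c("a", "b"), each = 30),
#'   value = c(rnorm(30), rnorm(30, sd = 3))
#' )
#' perm_dispersion_test(d, metric = "sd", n_perm = 199, seed = 1)
#' @export
perm_dispersion_test <- function(data, metric = c("sd", "mad", "gini"),
                                 n_perm = 1000, seed = NULL) {
  metric <- match.arg(metric)
  g <- two_groups(data)
  fn <- dispersion_metric(metric)
  d1 <- fn(g[[1]])
  d2 <- fn(g[[2]])
  if (!is.finite(d1) || !is.finite(d2)) {
    abort("group dispersion is not finite", class = "varhet_degenerate_error")
  }
  if (d1 == 0 && d2 == 0) {
    abort("both groups have zero dispersion", class = "varhet_degenerate_error")
  }
  eps <- .Machine$double.xmin
  if (d1 == 0 || d2 == 0) {
    warn("zero dispersion in one group; using the smallest positive value")
  }
  t_obs <- abs(log(max(d1, eps) / max(d2, eps)))

  pooled <- c(g[[1]], g[[2]])
  n1 <- length(g[[1]])
  n <- length(pooled)
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n, n1)
      p1 <- fn(pooled[idx])
      p2 <- fn(pooled[-idx])
      abs(log(max(p1, eps) / max(p2, eps)))
    }, numeric(1))
  })
  p <- (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
  new_test_result(paste0("perm_", metric), t_obs, p,
    n_resamples = n_perm, seed = seed,
    extras = list(dispersion = setNames(c(d1, d2), names(g)))
  )
}

#' Levene / Brown-Forsythe test for variance homogeneity
#'
#' One-way ANOVA on the absolute deviations `z_ij = |x_ij - center_j|`;
#' `center = "median"` gives the Brown-Forsythe variant (the default, being
#' robust to heavy tails), `center = "mean"` the classical Levene test.
#'
#' @param data Data frame with `group` (>= 2 levels) and `value`.
#' @param center Per-group centring statistic.
#' @return A one-row `vh_test` tibble; the statistic is the ANOVA F with
#'   `(k - 1, N - k)` degrees of freedom (stored in `extras`).
#' @export
levene_test <- function(data, center = c("median", "mean")) {
  center <- match.arg(center)
  data <- as_sample_set(data)
  cfun <- if (center == "median") stats::median else mean
  centers <- tapply(data$value, data$group, cfun)
  z <- abs(data$value - centers[as.integer(data$group)])
  if (stats::var(z) == 0) {
    abort("all absolute deviations identical; Levene statistic undefined",
      class = "varhet_degenerate_error"
    )
  }
  fit <- stats::anova(stats::aov(z ~ g, data = data.frame(z = z, g = data$group)))
  new_test_result(
    if (center == "median") "brown_forsythe" else "levene",
    fit$`F value`[1], fit$`Pr(>F)`[1],
    extras = list(df = c(fit$Df[1], fit$Df[2]), center = center)
  )
}

#' Tests for a mean difference between groups
#'
#' Standard one-way ANOVA, the Welch two-sample t-test, or a permutation test
#' of `|mean_1 - mean_2|` with the add-one p-value rule.
#'
#' @param data Data frame with `group` and `value`. ANOVA accepts any number
#'   of groups; the Welch and permutation tests require exactly two.
#' @param method `"welch_t"`, `"anova"` or `"perm_mean"`.
#' @param n_perm Permutations for `method = "perm_mean"`.
#' @param seed Optional integer seed (permutation method only).
#' @return A one-row `vh_test` tibble.
#' @export
mean_test <- function(data, method = c("welch_t", "anova", "perm_mean"),
                      n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  if (method == "anova") {
    data <- as_sample_set(data)
    fit <- stats::anova(stats::aov(value ~ group, data = data))
    return(new_test_result("anova", fit$`F value`[1], fit$`Pr(>F)`[1],
      extras = list(df = c(fit$Df[1], fit$Df[2]))
    ))
  }
  g <- two_groups(data)
  if (method == "welch_t") {
    ht <- stats::t.test(g[[1]], g[[2]])
    return(new_test_result("welch_t", unname(ht$statistic), ht$p.value,
      extras = list(df = unname(ht$parameter))
    ))
  }
  t_obs <- abs(mean(g[[1]]) - mean(g[[2]]))
  pooled <- c(g[[1]], g[[2]])
  n1 <- length(g[[1]])
  n <- length(pooled)
  sum_all <- sum(pooled)
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s1 <- sum(pooled[sample.int(n, n1)])
      abs(s1 / n1 - (sum_all - s1) / (n - n1))
    }, numeric(1))
  })
  p <- (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
  new_test_result("perm_mean", t_obs, p, n_resamples = n_perm, seed = seed)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the full distributions of two groups via the supremum distance
#' between their empirical CDFs.
#'
#' @param data Data frame with `group` (2 levels) and `value`.
#' @param exact Passed to [stats::ks.test()]; `NULL` lets it decide (exact
#'   for small samples, asymptotic otherwise).
#' @return A one-row `vh_test` tibble with the D statistic.
#' @export
ks_two_sample <- function(data, exact = NULL) {
  g <- two_groups(data)
  ht <- suppressWarnings(stats::ks.test(g[[1]], g[[2]], exact = exact))
  new_test_result("ks", unname(ht$statistic), ht$p.value)
}
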