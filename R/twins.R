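#' Cotwin discordance deltas from an expression matrix
#'
#' For each twin pair, computes per-feature expression discordance as the
#' value in the higher-covariate member (e.g. the heavier twin by BMI) minus
#' the value in the lower-covariate member. Under this orientation,
#' covariate-unrelated features bifurcate around delta = 0 while related
#' features shift away from 0. Pairs with tied covariates keep their input
#' order (first sample treated as the higher member) and are flagged.
#'
#' @param expr Expression matrix: a data frame whose first column is the
#'   feature identifier and remaining columns are samples, or a numeric
#'   matrix with feature rownames and sample colnames. Values are assumed
#'   already normalised/log-scaled.
#' @param meta Data frame with columns `sample`, `pair` and `covariate`;
#'   every pair must have exactly two members present in `expr`.
#' @return A `delta_matrix`: a tibble with a `feature` column and one column
#'   per pair, with pair orientation metadata in `attr(, "pairs")`.
#' @examples
#' expr <- matrix(rnorm(20), 5, 4,
#'   dimnames = list(paste0("g", 1:5), paste0("s", 1:4))
#' )
#' meta <- data.frame(
#'   sample = paste0("s", 1:4),
#'   pair = c("p1", "p1", "p2", "p2"),
#'   covariate = c(31, 24, 22, 28)
#' )
#' compute_deltas(expr, meta)
#' @export
compute_deltas <- function(expr, meta) {
  if (is.data.frame(expr)) {
    features <- as.character(expr[[1]])
    mat <- as.matrix(expr[, -1, drop = FALSE])
    rownames(mat) <- features
  } else {
    mat <- as.matrix(expr)
    features <- rownames(mat) %||% paste0("feature_", seq_len(nrow(mat)))
    rownames(mat) <- features
  }
  if (!all(c("sample", "pair", "covariate") %in% names(meta))) {
    abort("meta must have columns 'sample', 'pair' and 'covariate'",
      class = "varhet_input_contract_error"
    )
  }
  meta <- tibble::as_tibble(meta)
  missing <- setdiff(meta$sample, colnames(mat))
  if (length(missing) > 0) {
    abort(paste0("samples absent from the matrix: ", paste(missing, collapse = ", ")),
      class = "varhet_pair_error"
    )
  }
  by_pair <- split(seq_len(nrow(meta)), meta$pair)
  bad <- names(by_pair)[vapply(by_pair, length, integer(1)) != 2 |
    vapply(by_pair, function(i) any(is.na(meta$covariate[i])), logical(1))]
  if (length(bad) > 0) {
    abort(paste0(
      "pairs must have exactly 2 members with covariate values; offending: ",
      paste(bad, collapse = ", ")
    ), class = "varhet_pair_error")
  }

  pair_ids <- names(by_pair)
  orient <- lapply(pair_ids, function(p) {
    i <- by_pair[[p]]
    cov <- meta$covariate[i]
    tied <- cov[1] == cov[2]
    hi <- if (cov[1] >= cov[2]) i[1] else i[2] # declared order wins ties
    lo <- setdiff(i, hi)
    tibble::tibble(
      pair = p,
      higher = meta$sample[hi], lower = meta$sample[lo],
      covariate_higher = meta$covariate[hi], covariate_lower = meta$covariate[lo],
      tied = tied
    )
  })
  orient <- dplyr::bind_rows(orient)
  if (any(orient$tied)) {
    warn(paste0(
      sum(orient$tied), " pair(s) with tied covariates; ",
      "declared sample order used for orientation"
    ))
  }
  deltas <- mat[, orient$higher, drop = FALSE] - mat[, orient$lower, drop = FALSE]
  colnames(deltas) <- orient$pair
  out <- dplyr::bind_cols(
    tibble::tibble(feature = features),
    tibble::as_tibble(deltas)
  )
  attr(out, "pairs") <- orient
  class(out) <- c("delta_matrix", class(out))
  out
}

delta_values <- function(deltas) {
  as.matrix(deltas[, setdiff(names(deltas), "feature"), drop = FALSE])
}

#' Keep the most variable features of a delta matrix
#'
#' Ranks features by the standard deviation of their deltas across pairs and
#' keeps the top `k` (ties broken by input order). The default of 4000
#' matches the usual screening depth for genome-wide cotwin analyses.
#'
#' @param deltas A [compute_deltas()] result.
#' @param k Number of features to keep.
#' @return A `delta_matrix` with at most `k` rows.
#' @export
top_variable_features <- function(deltas, k = 4000) {
  stopifnot(inherits(deltas, "delta_matrix"))
  if (k > nrow(deltas)) {
    abort("k exceeds the number of features", class = "varhet_parameter_error")
  }
  sds <- apply(delta_values(deltas), 1, stats::sd)
  keep <- sort(head(order(-sds), k)) # stable under ties, preserves input order
  out <- deltas[keep, ]
  attr(out, "pairs") <- attr(deltas, "pairs")
  class(out) <- c("delta_matrix", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1),
#' returned in the input order.
#'
#' @param pvals Vector of p-values in `(0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]", class = "varhet_parameter_error")
  }
  p.adjust(pvals, method = "BH")
}

#' Screen a delta matrix for bimodal features
#'
#' Runs the parametric bootstrap likelihood-ratio test (1 vs 2 components,
#' [bootstrap_lrt()]) on every feature's delta vector, adjusts p-values by
#' Benjamini-Hochberg across all tested features, and excludes features whose
#' minority mode is too small to be trustworthy (guarding against outliers
#' masquerading as modes). A feature passes when its adjusted p-value is at
#' most `fdr_level` and its minority-mode proportion is at least
#' `min_mode_prop`.
#'
#' By default the minority proportion is the smaller fitted mixing weight;
#' `min_mode_basis = "classified"` uses the fraction of observations
#' classified to the minority component instead.
#'
#' @param deltas A [compute_deltas()] result (or any `delta_matrix`).
#' @param family Mixture family for the LRT (deltas of log-scale expression
#'   are conventionally modelled as normal).
#' @param n_boot Bootstrap replicates per feature. The default (200) is a
#'   desk-scale setting; genome-wide screens commonly use 10000.
#' @param fdr_level FDR threshold for the BH-adjusted p-values.
#' @param min_mode_prop Minimum minority-mode proportion.
#' @param min_mode_basis `"weight"` or `"classified"` (see above).
#' @param seed Root seed; each feature receives a derived seed.
#' @param ... Further EM settings passed to [bootstrap_lrt()] (e.g.
#'   `n_restarts`, `tol`).
#' @return A `screen_result` tibble with one row per feature: `feature`,
#'   `statistic`, `p_value`, `p_adjusted`, `minority_prop`, `pass`, `reason`
#'   (`NA`, `"fdr"`, `"min_mode"` or `"fit_failed"`).
#' @export
screen_bimodal_features <- function(deltas, family = "normal", n_boot = 200,
                                    fdr_level = 0.05, min_mode_prop = 0.10,
                                    min_mode_basis = c("weight", "classified"),
                                    seed = NULL, ...) {
  stopifnot(inherits(deltas, "delta_matrix"))
  min_mode_basis <- match.arg(min_mode_basis)
  mat <- delta_values(deltas)
  if (ncol(mat) < 10) {
    abort("need at least 10 pairs per feature", class = "varhet_size_error")
  }
  n_feat <- nrow(mat)
  stat <- p_raw <- minority <- rep(NA_real_, n_feat)
  failed <- rep(FALSE, n_feat)
  for (i in seq_len(n_feat)) {
    res <- tryCatch(
      bootstrap_lrt(mat[i, ], family,
        n_boot = n_boot,
        seed = if (is.null(seed)) NULL else derive_seed(seed, i, stream = 17L),
        ...
      ),
      error = function(e) NULL
    )
    if (is.null(res)) {
      failed[i] <- TRUE
      next
    }
    stat[i] <- res$lrt_statistic
    p_raw[i] <- res$p_value
    minority[i] <- if (min_mode_basis == "weight") {
      min(res$alt_fit$weights)
    } else {
      min(table(factor(classify_modes(res$alt_fit), levels = seq_len(res$alt_fit$K)))) /
        length(mat[i, ])
    }
  }
  p_adj <- rep(NA_real_, n_feat)
  tested <- !failed
  p_adj[tested] <- bh_adjust(p_raw[tested])
  pass <- tested & p_adj <= fdr_level & minority >= min_mode_prop
  reason <- rep(NA_character_, n_feat)
  reason[failed] <- "fit_failed"
  reason[tested & p_adj > fdr_level] <- "fdr"
  reason[tested & p_adj <= fdr_level & minority < min_mode_prop] <- "min_mode"
  out <- tibble::tibble(
    feature = deltas$feature, statistic = stat, p_value = p_raw,
    p_adjusted = p_adj, minority_prop = minority,
    pass = pass, reason = reason
  )
  class(out) <- c("screen_result", class(out))
  out
}

#' Chi-square association between mixture modes and an outcome grouping
#'
#' Cross-tabulates hard mode assignments (e.g. from [classify_modes()])
#' against an outcome label and applies Pearson's chi-square test without
#' continuity correction (the hand-computable statistic; Yates' correction is
#' available via `correct = TRUE`). Levels with zero marginal counts are
#' dropped with a warning; a warning is also raised when any expected count
#' falls below 5.
#'
#' @param mode_labels Vector of mode assignments.
#' @param outcome_labels Vector of outcome labels, same length.
#' @param correct Apply Yates' continuity correction?
#' @return A one-row `vh_test` tibble with the contingency table in
#'   `attr(, "extras")`.
#' @examples
#' mode_group_association(rep(1:2, each = 10), rep(c("poor", "good"), each = 10))
#' @export
mode_group_association <- function(mode_labels, outcome_labels, correct = FALSE) {
  if (length(mode_labels) != length(outcome_labels)) {
    abort("label vectors must have equal length", class = "varhet_parameter_error")
  }
  f1 <- if (is.factor(mode_labels)) mode_labels else factor(mode_labels)
  f2 <- if (is.factor(outcome_labels)) outcome_labels else factor(outcome_labels)
  if (nlevels(droplevels(f1)) < nlevels(f1) || nlevels(droplevels(f2)) < nlevels(f2)) {
    warn("dropping factor level(s) with zero marginal count")
  }
  f1 <- droplevels(f1)
  f2 <- droplevels(f2)
  if (nlevels(f1) < 2 || nlevels(f2) < 2) {
    abort("each label vector needs >= 2 observed levels", class = "varhet_design_error")
  }
  tab <- table(f1, f2)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  if (any(ht$expected < 5)) {
    warn("expected count below 5 in the contingency table; chi-square may be unreliable")
  }
  new_test_result("chisq_independence", unname(ht$statistic), ht$p.value,
    extras = list(table = tab, df = unname(ht$parameter), expected = ht$expected)
  )
}
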