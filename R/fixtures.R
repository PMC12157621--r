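#' Generate synthetic benchmark fixtures
#'
#' Writes small plain-text datasets emulating the study designs the package
#' targets, each with a known ground truth. Three kinds are available:
#'
#' * `"two_group_vh"`: a `group`/`value` CSV from a unimodal baseline and a
#'   mean/variance effect (two-group variance-heterogeneity design).
#'   Params: `baseline` ([dist_spec()]), `effect` ([effect_spec()]),
#'   `n_per_group`.
#' * `"bimodal_cohort"`: a single-column CSV drawn from a mixture, plus a
#'   ground-truth component label file. Params: `spec` ([mixture_spec()]),
#'   `n`.
#' * `"twin_matrix"`: a features-x-pairs delta CSV in which a planted subset
#'   of features is bimodal (majority mode at 0, minority mode displaced by
#'   `separation` noise-SD units with random sign and a minority weight
#'   drawn from `minority_range`), the rest unimodal around 0, plus a
#'   manifest naming the planted features. Defaults are sized like a typical
#'   cotwin screen: 146 pairs, 4000 features, 292 planted, minority weight
#'   at least 0.1.
#'
#' The same seed always produces byte-identical files.
#'
#' @param kind Fixture kind (see above).
#' @param dir Output directory (created if needed).
#' @param params Named list overriding the kind's defaults.
#' @param seed Integer seed.
#' @return (Invisibly) a list with the written `paths` and the generated
#'   tables.
#' @examples
#' \donttest{
#' out <- generate_fixture("bimodal_cohort",
#'   dir = tempdir(),
#'   params = list(n = 50), seed = 1
#' )
#' out$paths
#' }
#' @export
generate_fixture <- function(kind = c("two_group_vh", "bimodal_cohort", "twin_matrix"),
                             dir = ".", params = list(), seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(kind,
    two_group_vh = fixture_two_group_vh(dir, params, seed),
    bimodal_cohort = fixture_bimodal_cohort(dir, params, seed),
    twin_matrix = fixture_twin_matrix(dir, params, seed)
  )
}

fixture_two_group_vh <- function(dir, params, seed) {
  p <- modifyList(list(
    baseline = dist_spec("normal", mean = 0, sd = 1),
    effect = effect_spec(0, 2),
    n_per_group = 100L
  ), params)
  shifted <- apply_effect(p$baseline, p$effect)
  data <- with_seed(seed, tibble::tibble(
    group = rep(c("g1", "g2"), each = p$n_per_group),
    value = c(
      dist_sample(p$baseline, p$n_per_group),
      dist_sample(shifted, p$n_per_group)
    )
  ))
  path <- file.path(dir, "two_group_vh.csv")
  readr::write_csv(data, path, progress = FALSE)
  invisible(list(paths = path, data = data))
}

fixture_bimodal_cohort <- function(dir, params, seed) {
  p <- modifyList(list(
    spec = mixture_spec(
      list(
        dist_spec("normal", mean = 0, sd = 1),
        dist_spec("normal", mean = 4, sd = 1)
      ),
      weights = c(0.5, 0.5)
    ),
    n = 200L
  ), params)
  draw <- sample_mixture(p$spec, p$n, seed = seed)
  value_path <- file.path(dir, "bimodal_cohort.csv")
  label_path <- file.path(dir, "bimodal_cohort_labels.csv")
  readr::write_csv(draw["value"], value_path, progress = FALSE)
  readr::write_csv(draw["component"], label_path, progress = FALSE)
  invisible(list(paths = c(value_path, label_path), data = draw))
}

fixture_twin_matrix <- function(dir, params, seed) {
  p <- modifyList(list(
    n_pairs = 146L,
    n_features = 4000L,
    n_bimodal = 292L,
    separation = 4,
    noise_sd = 1,
    minority_range = c(0.1, 0.5)
  ), params)
  stopifnot(p$n_bimodal <= p$n_features)
  out <- with_seed(seed, {
    planted <- sort(sample.int(p$n_features, p$n_bimodal))
    is_bimodal <- seq_len(p$n_features) %in% planted
    w_minor <- ifelse(is_bimodal,
      runif(p$n_features, p$minority_range[1], p$minority_range[2]), NA
    )
    mu_minor <- ifelse(is_bimodal,
      sample(c(-1, 1), p$n_features, replace = TRUE) * p$separation * p$noise_sd, NA
    )
    mat <- matrix(rnorm(p$n_features * p$n_pairs, 0, p$noise_sd),
      nrow = p$n_features
    )
    for (i in planted) {
      minor <- runif(p$n_pairs) < w_minor[i]
      mat[i, minor] <- mat[i, minor] + mu_minor[i]
    }
    features <- sprintf("feature_%04d", seq_len(p$n_features))
    deltas <- dplyr::bind_cols(
      tibble::tibble(feature = features),
      tibble::as_tibble(
        matrix(mat,
          nrow = p$n_features,
          dimnames = list(NULL, sprintf("pair_%03d", seq_len(p$n_pairs)))
        )
      )
    )
    manifest <- tibble::tibble(
      feature = features, bimodal = is_bimodal,
      w_minor = w_minor, mu_minor = mu_minor
    )
    list(deltas = deltas, manifest = manifest)
  })
  attr(out$deltas, "pairs") <- NULL
  class(out$deltas) <- c("delta_matrix", class(out$deltas))
  delta_path <- file.path(dir, "twin_matrix.csv")
  manifest_path <- file.path(dir, "twin_matrix_manifest.csv")
  readr::write_csv(out$deltas, delta_path, progress = FALSE)
  readr::write_csv(out$manifest, manifest_path, progress = FALSE)
  invisible(list(
    paths = c(delta_path, manifest_path),
    deltas = out$deltas, manifest = out$manifest
  ))
}

#' Read a delta matrix written by [generate_fixture()] or external tools
#'
#' @param path CSV/TSV file whose first column is the feature identifier and
#'   remaining columns are per-pair delta values.
#' @return A `delta_matrix` tibble.
#' @export
read_delta_matrix <- function(path) {
  df <- read_table_auto(path)
  if (ncol(df) < 2) {
    abort("delta matrix needs a feature column plus pair columns",
      class = "varhet_input_contract_error"
    )
  }
  names(df)[1] <- "feature"
  df$feature <- as.character(df$feature)
  class(df) <- c("delta_matrix", class(df))
  df
}
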