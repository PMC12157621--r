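#' Derive a reproducible child seed
#'
#' Deterministically maps a root seed plus a replicate index (and an optional
#' stream label) to a new integer seed. Simulation loops give every replicate
#' its own derived seed, so extending a run with more replicates, or adding
#' further sample sizes to a power grid, never perturbs the replicates already
#' computed.
#'
#' @param seed Integer root seed.
#' @param index Replicate index (non-negative integer).
#' @param stream Optional stream label separating independent uses of the same
#'   root seed (e.g. one stream per sample size in a power grid).
#' @return An integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 1, stream = 100)
#' @export
derive_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.numeric(seed)) + as.numeric(index) * 40503 +
    as.numeric(stream) * 104729) %% m
  # two mixing steps of a Lehmer-style recurrence; constants fit in double
  x <- (x * 69069 + 1) %% m
  x <- (x * 69069 + 1) %% m
  as.integer(x) + 1L
}

# evaluate code under a seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
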