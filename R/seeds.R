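#' Derive a child seed from a master seed and a key
#'
#' All stochastic functions in dynmap draw their randomness from a single
#' integer master seed. Sub-streams for independent components (participants,
#' permutation ensembles, bootstrap draws, ...) are derived by mixing the
#' master seed with a string key through a small multiplicative hash, so that
#' regenerating any one component is independent of the order in which other
#' components were generated.
#'
#' @param seed Integer master seed.
#' @param key Character scalar (or integer) naming the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' split_seed(1, "timeseries")
#' split_seed(1, "timeseries") == split_seed(1, "timeseries")
#' @export
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste0(as.character(key), collapse = "|")
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m)
  for (code in utf8ToInt(key)) {
    # Horner-style rolling hash; doubles hold exact integers < 2^53 so the
    # intermediate products (< 2^31 * 131) never lose precision
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run an expression under a locally-set RNG state, restoring the caller's
# state afterwards. Everything random in the package funnels through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
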