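#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global random-number state temporarily replaced by a
#' stream seeded from `seed`, then restores the caller's state. All stochastic
#' operations in the package are routed through this helper so that a given
#' `(input, seed)` pair is reproducible without clobbering the user's RNG.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a top-level seed. Keeps results
# below 2^31 so they remain valid R integers.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9176) %% 2147483629)
}
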