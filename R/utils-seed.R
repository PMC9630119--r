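# RNG handling: every generator is a pure function of (arguments, seed).
# Seeds are applied locally so callers' RNG streams are left untouched.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' then restores the previous state. Used internally by every stochastic
#' function so that identical arguments always yield identical output.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministic affine map kept below 2^31 so that pipeline stages can be
#' re-run independently with reproducible, non-colliding streams.
#'
#' @param seed global integer seed.
#' @param offset non-negative integer stage offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), is.numeric(offset))
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2099 + as.numeric(offset) * 9973 + 1) %% 2147483647L
}
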