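`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All stochastic operations in the package take a single integer seed and
#' derive independent child streams from it, so a whole run is reproducible
#' from one number. The derivation is a fixed affine map modulo a Mersenne
#' prime; results stay within the 32-bit integer range R requires.
#'
#' @param seed master integer seed.
#' @param offset integer stream offset (each consumer uses its own).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 1000003 * as.numeric(offset)) %% 2147483647)
}

# set.seed only when a seed was supplied; NULL leaves the RNG stream alone
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}
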