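# Seed handling: every stochastic routine scopes its own RNG state so that
# calls are reproducible in isolation and never perturb the caller's stream.

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `code`,
#' and restores the previous state on exit.  Used by every sampling routine
#' in the package so that a `(function, seed)` pair is a complete description
#' of its randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  has_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used to give each umbrella window, string
#' walker or committor shot its own independent, reproducible stream.  The
#' result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  i <- as.double(index)
  # two rounds of a multiplicative-congruential mix, kept in double range
  s <- (m * 48271 + i * 104729 + 12345) %% 2147483629
  s <- (s * 69621 + 7) %% 2147483563
  as.integer(s)
}
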