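# Internal helpers: deterministic seed fan-out and scoped RNG use.

#' Derive a child seed
#'
#' Deterministically fans one master seed out to per-stage or per-subject
#' seeds so that every source of randomness in a run is reproducible from a
#' single integer. The mapping is a fixed affine congruence modulo
#' 2^31 - 1; results always fit in a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param i child index (integer >= 0; vectorized).
#' @return integer vector of child seeds.
#' @examples
#' childSeed(1, 1:5)
#' @export
childSeed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 104729 * as.numeric(i) + 1) %%
               2147483647)
}

# Evaluate expr with a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

# Stable 31-bit polynomial hash of a string (used for id-keyed fold
# assignment and config fingerprints; subject order must not matter).
stringHash <- function(s) {
  vapply(as.character(s), function(si) {
    h <- 0
    for (code in utf8ToInt(si)) h <- (h * 31 + code) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# z-score that leaves constant columns at zero instead of NaN
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
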