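# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Every stochastic operation in the
# package routes through this so that no call mutates global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer (reproducibility is required).")
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Clamp a numeric vector into [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Finite check that treats NA as non-finite.
all_finite <- function(x) all(is.finite(x))
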