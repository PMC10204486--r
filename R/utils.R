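# Internal utilities: seeded evaluation and seed fan-out.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. With seed = NULL the code runs on the
# ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

# Deterministically derive a per-stage / per-item child seed from a global
# seed. Keeps results below 2^31 so they remain valid R integers.
derive_seed <- function(seed, index) {
  seed <- as.double(seed)
  index <- as.double(index)
  as.integer((seed * 48271 + index * 96731 + 11) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
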