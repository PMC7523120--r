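# Small shared helpers.

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed stream, kept below 2^31.
derive_seed <- function(seed, key) {
  (as.numeric(seed) * 48271 + as.numeric(key) * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
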