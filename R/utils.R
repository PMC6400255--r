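# Run expr with a temporary RNG seed, restoring the caller's RNG state.
# Used wherever a statistic needs its own reproducible randomness (half-set
# splits) without disturbing the GA's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# %||% for default arguments
`%||%` <- function(a, b) if (is.null(a)) b else a
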