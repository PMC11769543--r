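# Small shared helpers.

# Deterministic rounding: halves away from zero (round() in R rounds to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run expr under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards. seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
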