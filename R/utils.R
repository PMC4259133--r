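# evaluate expr under a temporary RNG state when seed is non-NULL,
# restoring the caller's stream afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stream of sub-seeds from one master seed (all < 2^31)
.split_seed <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
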