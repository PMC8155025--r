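# Small internal helpers.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row-wise softmax of a matrix, numerically stable.
row_softmax <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Row-wise log-softmax.
row_log_softmax <- function(x) {
  m <- apply(x, 1, max)
  s <- x - m
  s - log(rowSums(exp(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
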