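# internal helpers shared across modules

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards.  seed = NULL means "use the ambient RNG stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# draw a sub-seed from the current stream (for nested deterministic calls)
drawSeed <- function() sample.int(.Machine$integer.max - 1L, 1L)

stopIfNot1 <- function(x, what) {
  if (length(x) != 1L || is.na(x)) stop("'", what, "' must be a single non-NA value")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
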