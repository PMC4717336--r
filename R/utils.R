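#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the state afterwards. With `seed = NULL` the expression runs
#' against the current stream. Used throughout so that every stochastic
#' operation is reproducible from its own seed without disturbing the
#' session RNG.
#'
#' @param seed integer scalar or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
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

# Derive a per-substream seed from a root seed and small integer offsets,
# kept inside the 32-bit integer range R requires.
deriveSeed <- function(root, ...) {
  offs <- c(...)
  s <- as.double(root)
  for (o in offs) s <- (s * 1009 + o) %% 2147483629
  as.integer(s)
}

# Unbiased sample moments used by the CLT diagnostics.
sampleSkewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}
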