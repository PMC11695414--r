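# Internal numeric helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "eegfuse_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "eegfuse_error")))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stopf("%s contains non-finite values", what, class = "eegfuse_validation_error")
  }
  invisible(x)
}

#' Row-wise softmax
#'
#' Numerically stable softmax applied independently to each row of a
#' matrix. Rows containing `-Inf` entries receive zero weight there.
#'
#' @param x numeric matrix of logits.
#' @return matrix of the same shape; every row sums to 1.
#' @keywords internal
#' @noRd
softmax_rows <- function(x) {
  # max.col is C-level; ties.method only affects which max is picked,
  # not its value
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# M + bias broadcast over rows, cheaper than sweep()
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Exact GELU: x * Phi(x); derivative Phi(x) + x * phi(x).
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}
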