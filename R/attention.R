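# Attention primitives. Everything downstream (both encoders and the
# cross-modal block) is built on these two operations.

#' Scaled dot-product attention
#'
#' For queries `Q` (`T x k`), keys `K` (`T x k`) and values `V`
#' (`T x m`), computes `weights[t, j] = softmax_j(s * q_t . k_j)` with
#' `s = 1/sqrt(k)` when `scale_by_sqrt_dim` is `TRUE` (the numerically
#' safer convention, default) and `s = 1` otherwise, and the context
#' `context[t] = sum_j weights[t, j] * v_j`.
#'
#' @param queries,keys numeric `T x k` matrices (same width).
#' @param values numeric `T x m` matrix.
#' @param scale_by_sqrt_dim scale logits by `1/sqrt(k)` (default `TRUE`).
#' @param knn_k optional integer: per-query top-k masking of the logits
#'   before the softmax (see [knn_mask_attention()]); `NULL` disables.
#' @return list with `context` (`T x m`) and `weights` (`T x T`, rows
#'   sum to 1).
#' @examples
#' a <- attention(matrix(1, 2, 1), matrix(c(0, log(3)), 2, 1),
#'                matrix(c(0, 1), 2, 1), scale_by_sqrt_dim = FALSE)
#' a$weights[1, ]  # 0.25 0.75
#' @export
attention <- function(queries, keys, values, scale_by_sqrt_dim = TRUE,
                      knn_k = NULL) {
  if (is.vector(queries)) queries <- matrix(queries, ncol = 1L)
  if (is.vector(keys)) keys <- matrix(keys, ncol = 1L)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  Tn <- nrow(queries)
  if (Tn < 1L) stopf("T must be >= 1", class = "eegfuse_validation_error")
  if (nrow(keys) != Tn || nrow(values) != Tn)
    stopf("queries, keys and values must share T", class = "eegfuse_validation_error")
  if (ncol(queries) != ncol(keys))
    stopf("queries and keys must share width k", class = "eegfuse_validation_error")
  assert_finite(queries, "queries"); assert_finite(keys, "keys")
  assert_finite(values, "values")
  s <- if (isTRUE(scale_by_sqrt_dim)) 1 / sqrt(ncol(queries)) else 1
  logits <- s * tcrossprod(queries, keys)
  weights <- if (is.null(knn_k)) softmax_rows(logits)
             else knn_mask_attention(logits, knn_k)
  list(context = weights %*% values, weights = weights)
}

#' Top-k (k-NN) masked row softmax
#'
#' Per row of a logit matrix, keeps the `k` largest entries (ties broken
#' toward the lower column index) and sets the rest to `-Inf` before the
#' row softmax — the sparse "k-NN attention" restriction of attention to
#' the `k` most similar keys per query.
#'
#' @param logit_matrix numeric `T x T` matrix of attention logits.
#' @param k number of surviving entries per row, `1 <= k <= T`.
#' @return `T x T` weight matrix; each row sums to 1 with at most `k`
#'   nonzero entries.
#' @export
knn_mask_attention <- function(logit_matrix, k) {
  if (!is.matrix(logit_matrix))
    stopf("logit_matrix must be a matrix", class = "eegfuse_validation_error")
  Tn <- ncol(logit_matrix)
  if (!is_count(k, 1L) || k > Tn)
    stopf("k must satisfy 1 <= k <= T", class = "eegfuse_validation_error")
  if (k == Tn) return(softmax_rows(logit_matrix))
  masked <- logit_matrix
  for (t in seq_len(nrow(logit_matrix))) {
    # order() is stable: ties resolve to the lower column index
    keep <- order(logit_matrix[t, ], decreasing = TRUE)[seq_len(k)]
    masked[t, -keep] <- -Inf
  }
  softmax_rows(masked)
}
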