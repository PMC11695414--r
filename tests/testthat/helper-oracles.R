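# Independent brute-force oracles: literal double-loop evaluations of
# the defining formulas, kept deliberately separate from the package's
# vectorized implementations.

oracle_softmax <- function(x) exp(x) / sum(exp(x))

# attention: weights[t, j] = exp(s q_t.k_j) / sum_j' exp(s q_t.k_j')
oracle_attention <- function(Q, K, V, scale = TRUE) {
  Tn <- nrow(Q)
  s <- if (scale) 1 / sqrt(ncol(Q)) else 1
  W <- matrix(0, Tn, Tn)
  ctx <- matrix(0, Tn, ncol(V))
  for (t in seq_len(Tn)) {
    logits <- vapply(seq_len(Tn), function(j) s * sum(Q[t, ] * K[j, ]), 0)
    W[t, ] <- oracle_softmax(logits)
    for (j in seq_len(Tn)) ctx[t, ] <- ctx[t, ] + W[t, j] * V[j, ]
  }
  list(context = ctx, weights = W)
}

# top-k masked softmax by explicit enumeration per row
oracle_knn <- function(L, k) {
  W <- matrix(0, nrow(L), ncol(L))
  for (t in seq_len(nrow(L))) {
    keep <- order(L[t, ], decreasing = TRUE)[seq_len(k)]
    e <- exp(L[t, keep])
    W[t, keep] <- e / sum(e)
  }
  W
}

# EEG encoder: same-padded conv, activation, positional add, attention
oracle_encode_eeg <- function(X, cfg, params) {
  Tn <- nrow(X); K <- cfg$conv_kernel; pad <- (K - 1) %/% 2
  Z <- matrix(0, Tn, cfg$d_h)
  for (t in seq_len(Tn)) {
    acc <- params$bc
    for (k in seq_len(K)) {
      src <- t + k - 1 - pad
      if (src >= 1 && src <= Tn) {
        Wk <- params$Wc[((k - 1) * cfg$d + 1):(k * cfg$d), , drop = FALSE]
        acc <- acc + drop(X[src, ] %*% Wk)
      }
    }
    Z[t, ] <- acc
  }
  H <- if (cfg$activation == "gelu") Z * pnorm(Z) else Z
  if (cfg$use_positional_encoding)
    H <- H + params$Pe[seq_len(Tn), , drop = FALSE]
  at <- oracle_attention(H %*% params$Wqe, H %*% params$Wke, H,
                         scale = cfg$scale_attention)
  list(h = H, ctx = at$context, attn = at$weights)
}

# video encoder: per-pixel spatial pooling then temporal attention
oracle_encode_video <- function(frames, cfg, params) {
  dm <- dim(frames); Tn <- dm[1]
  Fm <- matrix(0, Tn, cfg$h_v)
  for (t in seq_len(Tn)) {
    scores <- c(); embs <- NULL
    p <- 0
    for (x in seq_len(dm[3])) for (y in seq_len(dm[2])) {
      # pixel order must match the package: p = (x-1)*h + y
      p <- p + 1
      v <- frames[t, y, x, ]
      ev <- drop(v %*% params$Wemb) + params$bemb
      scores <- c(scores, sum(ev * params$usp))
      full <- if (cfg$use_spatial_positions) ev + params$Psp[p, ] else ev
      embs <- rbind(embs, full)
    }
    a <- oracle_softmax(scores)
    for (p in seq_along(a)) Fm[t, ] <- Fm[t, ] + a[p] * embs[p, ]
  }
  H <- if (cfg$use_positional_encoding)
    Fm + params$Pv[seq_len(Tn), , drop = FALSE] else Fm
  at <- oracle_attention(H %*% params$Wqv, H %*% params$Wkv, H,
                         scale = cfg$scale_attention)
  list(h = H, ctx = at$context, attn = at$weights)
}

# cross-modal fusion: attn[t,j] = softmax_j(e_t.v_j);
# cross[t] = sum_j attn[t,j] (e_j + v_j)
oracle_fuse <- function(E, V) {
  Tn <- nrow(E)
  A <- matrix(0, Tn, Tn)
  cross <- matrix(0, Tn, ncol(E))
  for (t in seq_len(Tn)) {
    logits <- vapply(seq_len(Tn), function(j) sum(E[t, ] * V[j, ]), 0)
    A[t, ] <- oracle_softmax(logits)
    for (j in seq_len(Tn)) cross[t, ] <- cross[t, ] + A[t, j] * (E[j, ] + V[j, ])
  }
  list(cross = cross, attn = A)
}

# confusion-matrix-from-scratch metrics oracle
oracle_metrics <- function(probs, labels) {
  C <- ncol(probs)
  pred <- apply(probs, 1, function(r) which(r == max(r))[1]) - 1
  acc <- mean(pred == labels)
  rec <- f1 <- auc <- rep(NA_real_, C)
  for (k in seq_len(C) - 1) {
    if (!any(labels == k)) next
    tp <- sum(labels == k & pred == k)
    fn <- sum(labels == k & pred != k)
    fp <- sum(labels != k & pred == k)
    r <- tp / (tp + fn)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k + 1] <- r
    f1[k + 1] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    pos <- probs[labels == k, k + 1]; neg <- probs[labels != k, k + 1]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    auc[k + 1] <- mean(cmp)
  }
  list(accuracy = acc, macro_recall = mean(rec, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE), macro_auc = mean(auc, na.rm = TRUE))
}

# small random fixtures
rand_model_inputs <- function(Tn, cfg, seed) {
  set.seed(seed)
  list(eeg = eeg_sequence(matrix(rnorm(Tn * cfg$d), Tn, cfg$d)),
       video = video_sequence(frames = array(rnorm(Tn * cfg$h * cfg$w * cfg$c),
                                             c(Tn, cfg$h, cfg$w, cfg$c))),
       labels = label_sequence(sample(0:(cfg$n_classes - 1), Tn, TRUE),
                               cfg$n_classes))
}

tiny_cfg <- function(...) {
  args <- list(d = 2, h = 3, w = 2, c = 1, h_v = 3, d_h = 4, d_f = 3,
               n_classes = 2, dropout_p = 0, max_T = 8)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}
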