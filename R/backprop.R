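# Analytic backpropagation through the full forward pass.  Gradients
# are returned as a named list mirroring model$params; correctness is
# pinned against central-difference numerical gradients in the tests.

backward_seq <- function(model, fwd) {
  cfg <- model$config; pp <- model$params; variant <- fwd$cache$variant
  ca <- fwd$cache
  probs <- fwd$probs
  Tn <- nrow(probs)
  Y <- matrix(0, Tn, ncol(probs))
  Y[cbind(seq_len(Tn), fwd$ylab + 1L)] <- 1
  dZ <- probs - Y                                    # dL/dlogits
  g <- list()
  if (cfg$head_mode == "per_sequence" && variant != "head_only") {
    g$Wh <- crossprod(ca$pooled, dZ)
    g$bh <- colSums(dZ)
    dpooled <- dZ %*% t(pp$Wh)
    dCx <- matrix(dpooled / ca$pool_T, ca$pool_T, ncol(dpooled), byrow = TRUE)
  } else {
    g$Wh <- crossprod(ca$Cx, dZ)
    g$bh <- colSums(dZ)
    dCx <- dZ %*% t(pp$Wh)
  }
  if (variant == "head_only") return(g)

  Tn <- nrow(dCx)
  # fusion backward
  if (variant == "no_eeg_stream") {
    dVf <- dCx; dEf <- NULL
  } else if (variant == "no_cross_modal") {
    dEf <- dCx; dVf <- dCx
  } else if (variant == "no_adaptive_attention") {
    dS2 <- matrix(colSums(dCx) / Tn, Tn, ncol(dCx), byrow = TRUE)
    dEf <- dS2; dVf <- dS2
  } else {
    Ax <- ca$Ax; S2 <- ca$S2
    dAx <- tcrossprod(dCx, S2)
    dS2 <- crossprod(Ax, dCx)
    dLx <- Ax * (dAx - rowSums(dAx * Ax))
    dEf <- dLx %*% ca$Vf + dS2
    dVf <- crossprod(dLx, ca$Ef) + dS2
  }

  # video projection + temporal attention
  g$Wpv <- crossprod(ca$Cv, dVf); g$bpv <- colSums(dVf)
  dCv <- dVf %*% t(pp$Wpv)
  tb <- temporal_attn_backward(dCv, ca$Hv, pp$Wqv, pp$Wkv, ca$atv)
  if (!is.null(tb$dWq)) { g$Wqv <- tb$dWq; g$Wkv <- tb$dWk }
  dHv <- tb$dH
  if (cfg$use_positional_encoding) {
    g$Pv <- matrix(0, cfg$max_T, cfg$h_v)
    g$Pv[seq_len(Tn), ] <- dHv
  }
  dFm <- dHv
  if (!is.null(ca$mask_v)) dFm <- dFm * ca$mask_v
  if (!is.null(ca$sp)) {
    sb <- spatial_backward(dFm, pp, cfg, ca$sp)
    g$Wemb <- sb$dWemb; g$bemb <- sb$dbemb; g$usp <- sb$dusp
    if (cfg$use_spatial_positions) g$Psp <- sb$dPsp
  }

  # EEG stream
  if (variant != "no_eeg_stream") {
    g$Wpe <- crossprod(ca$Ce, dEf); g$bpe <- colSums(dEf)
    dCe <- dEf %*% t(pp$Wpe)
    tb <- temporal_attn_backward(dCe, ca$He, pp$Wqe, pp$Wke, ca$ate)
    if (!is.null(tb$dWq)) { g$Wqe <- tb$dWq; g$Wke <- tb$dWk }
    dHe <- tb$dH
    if (cfg$use_positional_encoding) {
      g$Pe <- matrix(0, cfg$max_T, cfg$d_h)
      g$Pe[seq_len(Tn), ] <- dHe
    }
    dHr <- dHe
    if (!is.null(ca$mask_e)) dHr <- dHr * ca$mask_e
    dZc <- if (cfg$activation == "gelu") dHr * gelu_grad(ca$cv$Z) else dHr
    g$Wc <- crossprod(ca$cv$Xcat, dZc)
    g$bc <- colSums(dZc)
  }
  g
}

# Flatten a named parameter (or gradient) list to one numeric vector in
# the canonical order of model$params, and back.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    chunk <- vec[(pos + 1L):(pos + n)]
    out[[nm]] <- if (is.matrix(template[[nm]]))
      matrix(chunk, nrow(template[[nm]]), ncol(template[[nm]])) else chunk
    pos <- pos + n
  }
  out
}

# Gradients aligned to the template's order; absent entries are zero
# (e.g. positional rows beyond T are never touched).
grads_as_vector <- function(grads, template) {
  full <- lapply(stats::setNames(names(template), names(template)), function(nm) {
    gg <- grads[[nm]]
    if (is.null(gg)) {
      tt <- template[[nm]]
      if (is.matrix(tt)) matrix(0, nrow(tt), ncol(tt)) else numeric(length(tt))
    } else gg
  })
  unlist(full, use.names = FALSE)
}
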