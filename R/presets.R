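#' Desk-scale configuration presets
#'
#' `tiny_config()` is the model configuration used by the synthetic
#' benchmarks and the ablation harness: 16 x 16 x 1 frames, hidden
#' widths 16, dropout 0.5 (the reference protocol's value; at desk
#' scale it is what prevents the model from memorizing per-sequence
#' noise fingerprints instead of the planted signal — see the methods
#' vignette). `tiny_train_config()` is the matching training preset:
#' peak learning rate 0.003 (3x the reference 0.001: with only a few
#' hundred Adam steps per run, per-coordinate travel is bounded by
#' lr x steps and 0.001 cannot traverse the distance the spatial
#' attention scale must cover), clip threshold 1.0, weight decay 1e-4,
#' batch 32 (the reference setting for the smaller corpora), patience
#' 10, at most 60 epochs.
#'
#' @param T sequence length the preset should accommodate.
#' @param n_classes number of classes.
#' @param d EEG channel count.
#' @return a [model_config()].
#' @export
tiny_config <- function(T = 32L, n_classes = 2L, d = 8L) {
  model_config(d = d, h = 16L, w = 16L, c = 1L, h_v = 16L, d_h = 16L,
               d_f = 16L, n_classes = n_classes, conv_kernel = 3L,
               dropout_p = 0.5, max_T = max(64L, T))
}

#' @rdname tiny_config
#' @param seed training seed.
#' @param max_epochs epoch cap for the desk-scale runs.
#' @return a [train_config()] (for `tiny_train_config`).
#' @export
tiny_train_config <- function(seed = 1L, max_epochs = 60L) {
  train_config(eta_max = 0.003, tau = 1.0, weight_decay = 1e-4,
               batch_size = 32L, max_epochs = max_epochs, patience = 10L,
               seed = seed)
}
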