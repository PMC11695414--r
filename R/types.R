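# Domain containers. Light S3 wrappers over base matrices/arrays with
# validation at construction; the numeric payload is always reachable as
# a plain matrix/array so downstream linear algebra stays allocation-free.

#' EEG sequence container
#'
#' A multichannel EEG recording laid out as a `T x d` numeric matrix:
#' rows are time steps, columns are channels. Values are in arbitrary
#' units (typically microvolts); the sampling rate is carried as
#' metadata only.
#'
#' @param samples numeric `T x d` matrix (or vector, treated as one
#'   channel); all entries must be finite, `T >= 1`, `d >= 1`.
#' @param sampling_rate sampling frequency in Hz (metadata).
#' @return an object of class `eeg_sequence`.
#' @examples
#' x <- eeg_sequence(matrix(rnorm(64), 32, 2), sampling_rate = 128)
#' dim(x$samples)
#' @export
eeg_sequence <- function(samples, sampling_rate = 128) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("samples must be a numeric matrix", class = "eegfuse_validation_error")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stopf("samples must have T >= 1 rows and d >= 1 columns",
          class = "eegfuse_validation_error")
  assert_finite(samples, "EEG samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stopf("sampling_rate must be a positive scalar", class = "eegfuse_validation_error")
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "eeg_sequence")
}

#' Video sequence container
#'
#' Either raw frames (`T x h x w x c` array) or pre-featurized per-frame
#' vectors (`T x h_v` matrix). Exactly one of `frames`/`features` must
#' be supplied.
#'
#' @param frames numeric 4-d array `T x h x w x c`, finite.
#' @param features numeric `T x h_v` matrix, finite.
#' @return an object of class `video_sequence`.
#' @export
video_sequence <- function(frames = NULL, features = NULL) {
  if (!is.null(frames) && !is.null(features))
    stopf("supply frames OR features, not both", class = "eegfuse_validation_error")
  if (is.null(frames) && is.null(features))
    stopf("supply frames or features", class = "eegfuse_validation_error")
  if (!is.null(frames)) {
    if (!is.array(frames) || length(dim(frames)) != 4L)
      stopf("frames must be a T x h x w x c array", class = "eegfuse_validation_error")
    if (any(dim(frames) < 1L))
      stopf("all frame dimensions must be >= 1", class = "eegfuse_validation_error")
    assert_finite(frames, "video frames")
  } else {
    if (is.vector(features)) features <- matrix(features, ncol = 1L)
    if (!is.matrix(features))
      stopf("features must be a T x h_v matrix", class = "eegfuse_validation_error")
    assert_finite(features, "video features")
  }
  structure(list(frames = frames, features = features), class = "video_sequence")
}

#' Per-time-step label sequence
#'
#' Integer class labels, 0-based, one per time step. `labels` may be
#' supplied 1-based with `one_based = TRUE` (the common layout of label
#' CSVs exported by other tools).
#'
#' @param labels integer vector, each in `0..n_classes-1`.
#' @param n_classes number of classes `|C| >= 2`.
#' @param class_names optional character vector of length `n_classes`.
#' @param one_based if `TRUE`, `labels` are 1-based and are shifted down.
#' @return an object of class `label_sequence`.
#' @export
label_sequence <- function(labels, n_classes, class_names = NULL, one_based = FALSE) {
  labels <- as.integer(labels)
  if (one_based) labels <- labels - 1L
  if (!is_count(n_classes, 2L))
    stopf("n_classes must be an integer >= 2", class = "eegfuse_validation_error")
  n_classes <- as.integer(n_classes)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= n_classes))
    stopf("labels must lie in 0..n_classes-1", class = "eegfuse_validation_error")
  if (!is.null(class_names) && length(class_names) != n_classes)
    stopf("class_names must have length n_classes", class = "eegfuse_validation_error")
  structure(list(labels = labels, n_classes = n_classes, class_names = class_names),
            class = "label_sequence")
}

#' Model architecture configuration
#'
#' All architectural knobs of the two-stream model. Dimensions follow
#' the usual symbols: `d` EEG channels, `h x w x c` frame geometry,
#' `d_h` EEG hidden width, `h_v` video hidden width, `d_f` shared fusion
#' width, `n_classes` output classes.
#'
#' @param d EEG channel count.
#' @param h,w,c frame height, width and channel count.
#' @param h_v video hidden width.
#' @param d_h EEG hidden width.
#' @param d_f shared fusion width.
#' @param n_classes number of classes (>= 2).
#' @param conv_kernel odd temporal convolution width (default 3).
#' @param dropout_p dropout probability in `[0, 1)` (default 0.5).
#' @param use_knn_attention apply per-query top-k masking to temporal
#'   attention logits (default `FALSE`).
#' @param knn_k the `k` of top-k masking (must satisfy `1 <= k <= T` at
#'   run time).
#' @param use_positional_encoding learned additive per-time-step
#'   embedding on both streams (default `TRUE`).
#' @param use_spatial_positions learned additive per-pixel embedding in
#'   the spatial pooling stage (default `TRUE`).
#' @param activation nonlinearity after the temporal convolution:
#'   `"gelu"` or `"linear"`.
#' @param max_T capacity of the learned positional embeddings; inputs
#'   with `T > max_T` are rejected when positional encoding is on.
#' @param scale_attention use the `1/sqrt(k)` logit scale in temporal
#'   attention (default `TRUE`; cross-modal fusion logits are always the
#'   raw dot products).
#' @param head_mode `"per_step"` (one prediction per time step) or
#'   `"per_sequence"` (mean-pooled fused context before the head).
#' @return an object of class `model_config`.
#' @export
model_config <- function(d = 8L, h = 16L, w = 16L, c = 1L,
                         h_v = 16L, d_h = 16L, d_f = 16L, n_classes = 2L,
                         conv_kernel = 3L, dropout_p = 0.5,
                         use_knn_attention = FALSE, knn_k = 8L,
                         use_positional_encoding = TRUE,
                         use_spatial_positions = TRUE,
                         activation = c("gelu", "linear"),
                         max_T = 64L, scale_attention = TRUE,
                         head_mode = c("per_step", "per_sequence")) {
  activation <- match.arg(activation)
  head_mode <- match.arg(head_mode)
  for (nm in c("d", "h", "w", "c", "h_v", "d_h", "d_f", "n_classes",
               "conv_kernel", "knn_k", "max_T")) {
    if (!is_count(get(nm), 1L)) stopf("%s must be a positive integer", nm,
                                      class = "eegfuse_validation_error")
  }
  if (n_classes < 2L) stopf("n_classes must be >= 2", class = "eegfuse_validation_error")
  if (conv_kernel %% 2L == 0L)
    stopf("conv_kernel must be odd", class = "eegfuse_validation_error")
  if (!is.numeric(dropout_p) || dropout_p < 0 || dropout_p >= 1)
    stopf("dropout_p must be in [0, 1)", class = "eegfuse_validation_error")
  structure(list(d = as.integer(d), h = as.integer(h), w = as.integer(w),
                 c = as.integer(c), h_v = as.integer(h_v), d_h = as.integer(d_h),
                 d_f = as.integer(d_f), n_classes = as.integer(n_classes),
                 conv_kernel = as.integer(conv_kernel), dropout_p = as.numeric(dropout_p),
                 use_knn_attention = isTRUE(use_knn_attention),
                 knn_k = as.integer(knn_k),
                 use_positional_encoding = isTRUE(use_positional_encoding),
                 use_spatial_positions = isTRUE(use_spatial_positions),
                 activation = activation, max_T = as.integer(max_T),
                 scale_attention = isTRUE(scale_attention),
                 head_mode = head_mode),
            class = "model_config")
}

#' Training configuration
#'
#' Optimizer / schedule / regularization knobs. Defaults follow the
#' reference training protocol: Adam at a peak learning rate of 0.001
#' with a cosine cyclic schedule, weight decay 1e-4, gradient-norm clip
#' threshold 1.0, batch size 64, early-stopping patience 10.
#'
#' @param eta_min,eta_max minimum / maximum learning rate
#'   (`0 <= eta_min < eta_max`).
#' @param T_max iterations (optimizer steps) per cosine cycle; `NULL`
#'   defaults to 10 epochs' worth of steps at train time.
#' @param tau gradient-norm clip threshold (> 0).
#' @param weight_decay decoupled weight-decay coefficient.
#' @param coupled_weight_decay if `TRUE`, add `weight_decay * theta` to
#'   the raw gradient instead (classic L2 coupling through Adam moments).
#' @param batch_size sequences per optimizer step.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param seed integer seed driving all training randomness.
#' @return an object of class `train_config`.
#' @export
train_config <- function(eta_min = 0, eta_max = 0.001, T_max = NULL,
                         tau = 1.0, weight_decay = 1e-4,
                         coupled_weight_decay = FALSE,
                         batch_size = 64L, max_epochs = 100L,
                         patience = 10L, seed = 1L) {
  if (!is.numeric(eta_min) || !is.numeric(eta_max) || eta_min < 0 || eta_min >= eta_max)
    stopf("need 0 <= eta_min < eta_max", class = "eegfuse_validation_error")
  if (!is.null(T_max) && !is_count(T_max, 1L))
    stopf("T_max must be a positive integer or NULL", class = "eegfuse_validation_error")
  if (!is.numeric(tau) || tau <= 0)
    stopf("tau must be > 0", class = "eegfuse_validation_error")
  if (!is_count(patience, 1L))
    stopf("patience must be an integer >= 1", class = "eegfuse_validation_error")
  if (!is_count(batch_size, 1L) || !is_count(max_epochs, 0L))
    stopf("batch_size >= 1 and max_epochs >= 0 required",
          class = "eegfuse_validation_error")
  structure(list(eta_min = eta_min, eta_max = eta_max,
                 T_max = if (is.null(T_max)) NULL else as.integer(T_max),
                 tau = tau, weight_decay = weight_decay,
                 coupled_weight_decay = isTRUE(coupled_weight_decay),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Ablation variant specification
#'
#' @param variant one of `"full"`, `"no_cross_modal"`,
#'   `"no_adaptive_attention"`, `"no_eeg_stream"`.
#' @return an object of class `ablation_spec`.
#' @export
ablation_spec <- function(variant = c("full", "no_cross_modal",
                                      "no_adaptive_attention", "no_eeg_stream")) {
  variant <- match.arg(variant)
  structure(list(variant = variant), class = "ablation_spec")
}

#' Synthetic dataset specification
#'
#' Describes a paired EEG/video dataset with planted class signal. The
#' four regimes control where the label is decodable from:
#' `eeg_only` (EEG spectral signature, random video trajectory),
#' `video_only`, `redundant` (both), and `interaction_only` (binary bits
#' planted separately in each modality, label = XOR; only the joint
#' signal is informative).
#'
#' @param n_sequences number of sequences (>= n_classes).
#' @param T time steps / frames per sequence.
#' @param d EEG channels.
#' @param h,w,c frame geometry.
#' @param n_classes number of classes (must be 2 for `interaction_only`).
#' @param regime one of the four signal regimes.
#' @param snr amplitude ratio of planted signal to unit noise (> 0).
#' @param sampling_rate EEG sampling rate in Hz.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_sequences = 400L, T = 32L, d = 8L,
                       h = 16L, w = 16L, c = 1L, n_classes = 2L,
                       regime = c("redundant", "eeg_only", "video_only",
                                  "interaction_only"),
                       snr = 2, sampling_rate = 128, seed = 1L) {
  regime <- match.arg(regime)
  if (!is_count(n_sequences, 1L) || n_sequences < n_classes)
    stopf("n_sequences must be >= n_classes", class = "eegfuse_validation_error")
  if (!is_count(T, 1L) || !is_count(d, 1L))
    stopf("T and d must be positive integers", class = "eegfuse_validation_error")
  if (!is.numeric(snr) || snr <= 0)
    stopf("snr must be > 0", class = "eegfuse_validation_error")
  if (regime == "interaction_only" && n_classes != 2L)
    stopf("interaction_only requires n_classes == 2 (XOR construction)",
          class = "eegfuse_validation_error")
  structure(list(n_sequences = as.integer(n_sequences), T = as.integer(T),
                 d = as.integer(d), h = as.integer(h), w = as.integer(w),
                 c = as.integer(c), n_classes = as.integer(n_classes),
                 regime = regime, snr = as.numeric(snr),
                 sampling_rate = as.numeric(sampling_rate),
                 seed = as.integer(seed)),
            class = "synth_spec")
}
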