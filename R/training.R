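# Training strategy: cosine cyclic learning rate with warm restarts,
# global gradient-norm clipping, Adam with decoupled weight decay,
# early stopping, and the ablation builders.

#' Cosine cyclic learning rate with warm restarts
#'
#' `eta = eta_min + (eta_max - eta_min)/2 * (1 + cos(pi * t/T_max))`
#' with `t = t_cur mod T_max`, so the rate decays from `eta_max` to
#' `eta_min` over each cycle and restarts at `eta_max`.
#'
#' @param t_cur current iteration (integer >= 0; taken modulo `T_max`).
#' @param cfg a [train_config()]; `cfg$T_max` must be set here.
#' @return the learning rate, always within `[eta_min, eta_max]`.
#' @export
cyclic_lr <- function(t_cur, cfg) {
  T_max <- cfg$T_max
  if (is.null(T_max) || T_max < 1L)
    stopf("T_max must be a positive integer", class = "eegfuse_validation_error")
  if (any(t_cur < 0)) stopf("t_cur must be >= 0", class = "eegfuse_validation_error")
  t <- t_cur %% T_max
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) * (1 + cos(pi * t / T_max))
}

#' Global gradient-norm clipping
#'
#' `g_clipped = g / max(1, ||g|| / tau)`: the identity whenever
#' `||g|| <= tau`, otherwise a rescale to norm exactly `tau`. Direction
#' is always preserved.
#'
#' @param g numeric gradient vector (finite).
#' @param tau clip threshold (> 0).
#' @return the clipped gradient.
#' @export
clip_gradient <- function(g, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stopf("tau must be > 0", class = "eegfuse_validation_error")
  assert_finite(g, "gradient")
  g / max(1, sqrt(sum(g^2)) / tau)
}

#' Early-stopping check
#'
#' Stops once the best (minimum) validation loss lies `patience` or more
#' epochs in the past; ties resolve to the earliest epoch. (This matches
#' the usual "no improvement for `patience` consecutive epochs" rule.)
#'
#' @param val_losses numeric vector of per-epoch validation losses so far.
#' @param patience integer >= 1.
#' @return list with `stop` (flag) and `best_epoch` (1-based index of
#'   the best epoch; `NA` for an empty history).
#' @export
early_stop_check <- function(val_losses, patience) {
  if (!is_count(patience, 1L))
    stopf("patience must be an integer >= 1", class = "eegfuse_validation_error")
  if (length(val_losses) == 0L)
    return(list(stop = FALSE, best_epoch = NA_integer_))
  best <- which.min(val_losses)            # earliest on ties
  list(stop = (length(val_losses) - best) >= patience,
       best_epoch = as.integer(best))
}

#' Build an ablation variant of the model
#'
#' `no_cross_modal` replaces the cross-modal attention by the unweighted
#' per-step sum `ctx_eeg[t] + ctx_video[t]`; `no_adaptive_attention`
#' replaces the temporal attention poolings (EEG, video and cross) by
#' uniform `1/T` averaging (spatial attention is kept); `no_eeg_stream`
#' feeds the head from the projected video context alone.
#'
#' @param cfg a [model_config()].
#' @param spec an [ablation_spec()] (or a variant name).
#' @param seed initialization seed.
#' @return an `eegfuse_model`.
#' @export
build_ablation <- function(cfg, spec, seed = 1L) {
  variant <- if (inherits(spec, "ablation_spec")) spec$variant else spec
  if (!variant %in% c("full", "no_cross_modal", "no_adaptive_attention",
                      "no_eeg_stream"))
    stopf("unknown ablation variant '%s'", variant,
          class = "eegfuse_validation_error")
  build_model(cfg, variant, seed)
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(theta, g, st, lr, weight_decay, coupled, eps = 1e-8,
                      beta1 = 0.9, beta2 = 0.999) {
  if (coupled) g <- g + weight_decay * theta
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  theta <- theta - lr * mh / (sqrt(vh) + eps)
  if (!coupled) theta <- theta - lr * weight_decay * theta
  list(theta = theta, state = st)
}

#' Train a model
#'
#' Minibatch training with Adam (decoupled weight decay by default),
#' cosine cyclic learning rate, global gradient-norm clipping and early
#' stopping on the validation loss. Fully deterministic given
#' `cfg$seed`: two runs with identical inputs produce bit-identical
#' records and parameter trajectories.
#'
#' @param model an `eegfuse_model` from [build_model()] /
#'   [build_ablation()].
#' @param data a dataset: list of elements each holding `eeg`
#'   ([eeg_sequence()]), `video` ([video_sequence()]) and `labels`
#'   ([label_sequence()]), e.g. from [generate_synthetic()].
#' @param split list with integer index vectors `train` and `val`
#'   (disjoint), e.g. from [holdout_split()].
#' @param cfg a [train_config()]. A `NULL` `cfg$T_max` defaults to
#'   10 epochs' worth of optimizer steps.
#' @return list with `model` (parameters of the best validation epoch)
#'   and `record` (class `train_record`): per-epoch `train_loss`,
#'   `val_loss`, `lr_first_step`, per-step `lr`, `best_epoch`,
#'   `stop_epoch`, and `aborted` flag (non-finite loss encountered).
#' @export
train_model <- function(model, data, split, cfg) {
  stopifnot(inherits(model, "eegfuse_model"), inherits(cfg, "train_config"))
  if (length(intersect(split$train, split$val)) > 0L)
    stopf("train and validation splits must be disjoint",
          class = "eegfuse_validation_error")
  n_train <- length(split$train)
  steps_per_epoch <- max(1L, ceiling(n_train / cfg$batch_size))
  if (is.null(cfg$T_max)) cfg$T_max <- steps_per_epoch * 10L
  template <- model$params
  theta <- flatten_params(template)
  st <- adam_init(theta)
  rec <- list(train_loss = numeric(0), val_loss = numeric(0),
              lr_first_step = numeric(0), lr = numeric(0),
              best_epoch = NA_integer_, stop_epoch = 0L, aborted = FALSE)
  best_theta <- theta
  if (cfg$max_epochs == 0L) {
    rec$stop_epoch <- 0L
    return(list(model = model, record = structure(rec, class = "train_record")))
  }
  # per-sequence input unrolling is epoch-invariant: do it once
  preps <- vector("list", length(data))
  for (i in sort(unique(c(split$train, split$val))))
    preps[[i]] <- prepare_seq(model, data[[i]]$eeg, data[[i]]$video)
  set.seed(cfg$seed)
  step <- 0L
  val_losses <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- split$train[sample.int(n_train)]
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    epoch_losses <- numeric(0)
    lr_first <- NA_real_
    for (b in batches) {
      lr <- cyclic_lr(step, cfg)
      if (is.na(lr_first)) lr_first <- lr
      model$params <- unflatten_params(theta, template)
      gacc <- numeric(length(theta))
      bloss <- 0
      for (i in b) {
        fwd <- forward_seq(model, data[[i]]$eeg, data[[i]]$video,
                           data[[i]]$labels, train = TRUE, prep = preps[[i]])
        bloss <- bloss + fwd$loss
        gacc <- gacc + grads_as_vector(backward_seq(model, fwd), template)
      }
      bloss <- bloss / length(b)
      gacc <- gacc / length(b)
      if (!is.finite(bloss) || !all(is.finite(gacc))) {
        rec$aborted <- TRUE
        rec$stop_epoch <- epoch
        rec$train_loss <- c(rec$train_loss, bloss)
        model$params <- unflatten_params(best_theta, template)
        return(list(model = model, record = structure(rec, class = "train_record")))
      }
      gacc <- clip_gradient(gacc, cfg$tau)
      up <- adam_step(theta, gacc, st, lr, cfg$weight_decay,
                      cfg$coupled_weight_decay)
      theta <- up$theta; st <- up$state
      rec$lr <- c(rec$lr, lr)
      epoch_losses <- c(epoch_losses, bloss)
      step <- step + 1L
    }
    model$params <- unflatten_params(theta, template)
    vloss <- mean(vapply(split$val, function(i) {
      forward_seq(model, data[[i]]$eeg, data[[i]]$video,
                  data[[i]]$labels, train = FALSE, prep = preps[[i]])$loss
    }, numeric(1)))
    val_losses <- c(val_losses, vloss)
    rec$train_loss <- c(rec$train_loss, mean(epoch_losses))
    rec$val_loss <- c(rec$val_loss, vloss)
    rec$lr_first_step <- c(rec$lr_first_step, lr_first)
    es <- early_stop_check(val_losses, cfg$patience)
    if (identical(es$best_epoch, as.integer(epoch))) best_theta <- theta
    rec$best_epoch <- es$best_epoch
    rec$stop_epoch <- epoch
    if (es$stop) break
  }
  model$params <- unflatten_params(best_theta, template)
  list(model = model, record = structure(rec, class = "train_record"))
}

#' Serialize a training record to CSV
#'
#' Columns: `epoch`, `train_loss`, `val_loss`, `lr_first_step`.
#'
#' @param record a `train_record` from [train_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_record <- function(record, path) {
  ep <- seq_along(record$train_loss)
  df <- data.frame(epoch = ep,
                   train_loss = sprintf("%.17g", record$train_loss),
                   val_loss = sprintf("%.17g", record$val_loss[ep]),
                   lr_first_step = sprintf("%.17g", record$lr_first_step[ep]))
  data.table::fwrite(df, path)
  invisible(path)
}
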