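# Metric suite (accuracy, macro recall / F1 / one-vs-rest AUC) and the
# ablation harness.  All macro averages are unweighted class means,
# flagged in every report; AUC uses the rank statistic with midranks
# for ties, so it is invariant under strictly monotone score transforms.

binary_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)                       # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Computes accuracy, per-class recall, precision, F1 and one-vs-rest
#' AUC, plus their macro (unweighted mean) aggregates. Predicted classes
#' are the row-wise argmax of `probs` with ties broken toward the lower
#' class index. Classes absent from `labels` have undefined recall/AUC;
#' they are excluded from the macro means and listed in `warnings`.
#'
#' @param probs `N x n_classes` probability (or score) matrix; rows must
#'   sum to 1.
#' @param labels length-`N` 0-based integer labels (or a
#'   [label_sequence()]).
#' @param n_parameters,flops optional model accounting numbers carried
#'   into the report.
#' @return an object of class `metric_report`: `accuracy`,
#'   `macro_recall`, `macro_f1`, `macro_auc`, `n_parameters`, `flops`,
#'   `per_class` data frame, `averaging = "macro"` and `warnings`.
#' @export
classification_metrics <- function(probs, labels, n_parameters = NA_integer_,
                                   flops = NA_real_) {
  if (inherits(labels, "label_sequence")) labels <- labels$labels
  labels <- as.integer(labels)
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  if (nrow(probs) != length(labels))
    stopf("probs rows != labels length", class = "eegfuse_validation_error")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stopf("probability rows must sum to 1", class = "eegfuse_validation_error")
  C <- ncol(probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  # integer-count form: accuracy == 1 - misclassified/N exactly
  acc <- 1 - sum(pred != labels) / length(labels)
  warnings <- character(0)
  per <- data.frame(class = seq_len(C) - 1L, support = 0L, recall = NA_real_,
                    precision = NA_real_, f1 = NA_real_, auc = NA_real_)
  for (k in seq_len(C) - 1L) {
    tp <- sum(pred == k & labels == k)
    fp <- sum(pred == k & labels != k)
    fn <- sum(pred != k & labels == k)
    sup <- sum(labels == k)
    per$support[k + 1L] <- sup
    if (sup == 0L) {
      warnings <- c(warnings, sprintf(
        "class %d absent from labels; recall/F1/AUC undefined and excluded from macro means", k))
      next
    }
    rec <- tp / (tp + fn)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[k + 1L] <- rec
    per$precision[k + 1L] <- prec
    per$f1[k + 1L] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per$auc[k + 1L] <- binary_auc(probs[, k + 1L], labels == k)
  }
  structure(list(accuracy = acc,
                 macro_recall = mean(per$recall, na.rm = TRUE),
                 macro_f1 = mean(per$f1, na.rm = TRUE),
                 macro_auc = mean(per$auc, na.rm = TRUE),
                 n_parameters = n_parameters, flops = flops,
                 per_class = per, averaging = "macro", warnings = warnings),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> (macro averaging) acc=%.4f recall=%.4f f1=%.4f auc=%.4f\n",
    x$accuracy, x$macro_recall, x$macro_f1, x$macro_auc))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# Sequence-level class probabilities on a set of indices: per-step
# probabilities averaged over the sequence (a single row already for
# per-sequence heads).
sequence_probs <- function(model, data, idx) {
  t(vapply(idx, function(i) {
    colMeans(forward_seq(model, data[[i]]$eeg, data[[i]]$video,
                         train = FALSE)$probs)
  }, numeric(model$config$n_classes)))
}

#' Evaluate a model on a held-out index set
#'
#' @param model an `eegfuse_model`.
#' @param data an `eegfuse_dataset`.
#' @param idx integer indices to evaluate on.
#' @return a `metric_report` (sequence-level: per-step probabilities are
#'   averaged within each sequence before the argmax).
#' @export
evaluate_model <- function(model, data, idx) {
  probs <- sequence_probs(model, data, idx)
  classification_metrics(probs, dataset_classes(data)[idx],
                         n_parameters = count_parameters(model$config, model$variant),
                         flops = estimate_flops(model$config,
                                                attr(data, "spec")$T %||% nrow(probs),
                                                model$variant))
}

#' Run the ablation suite
#'
#' Trains the requested model variants per seed on identical synthetic
#' data and splits, evaluates each on the held-out test set, and
#' reports per-variant medians and interquartile ranges across seeds in
#' a machine-readable table (accuracy, recall, F1, AUC, parameters,
#' FLOPs).  Spread is reported as median and IQR over seeds — no
#' hypothesis test is claimed.  A training abort marks that cell failed
#' and the suite continues.
#'
#' @param spec a [synth_spec()]; `spec$seed` is combined with each
#'   entry of `seeds` to derive the data/split/training seeds.
#' @param cfg a [train_config()].
#' @param seeds integer vector of at least 3 seeds.
#' @param model_cfg a [model_config()]; defaults to a config matching
#'   `spec`'s geometry.
#' @param variants which variants to run (default all four).
#' @param fractions split fractions passed to [holdout_split()].
#' @return list with `table` (data frame: variant, median and IQR of
#'   each metric, n_parameters, flops, n_failed) and `runs` (data frame
#'   of every individual run).
#' @export
run_ablation_suite <- function(spec, cfg, seeds,
                               model_cfg = NULL,
                               variants = c("full", "no_cross_modal",
                                            "no_adaptive_attention",
                                            "no_eeg_stream"),
                               fractions = c(0.7, 0.15, 0.15)) {
  if (length(seeds) < 3L)
    stopf("need at least 3 seeds", class = "eegfuse_validation_error")
  if (is.null(model_cfg))
    model_cfg <- model_config(d = spec$d, h = spec$h, w = spec$w, c = spec$c,
                              n_classes = spec$n_classes, max_T = spec$T)
  runs <- list()
  for (s in seeds) {
    sub <- derive_seeds(spec$seed + s, 3L)
    spec_s <- spec; spec_s$seed <- sub[1L]
    data <- generate_synthetic(spec_s)
    split <- holdout_split(data, fractions, seed = sub[2L])
    for (v in variants) {
      model <- build_ablation(model_cfg, v, seed = sub[3L])
      cfg_s <- cfg; cfg_s$seed <- sub[3L]
      fit <- train_model(model, data, split, cfg_s)
      if (fit$record$aborted) {
        runs[[length(runs) + 1L]] <- data.frame(
          variant = v, seed = s, failed = TRUE, accuracy = NA_real_,
          recall = NA_real_, f1 = NA_real_, auc = NA_real_,
          n_parameters = count_parameters(model_cfg, v),
          flops = estimate_flops(model_cfg, spec$T, v))
        next
      }
      rep <- evaluate_model(fit$model, data, split$test)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = v, seed = s, failed = FALSE, accuracy = rep$accuracy,
        recall = rep$macro_recall, f1 = rep$macro_f1, auc = rep$macro_auc,
        n_parameters = rep$n_parameters, flops = rep$flops)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- lapply(split(runs, factor(runs$variant, levels = variants)), function(df) {
    q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                     names = FALSE)
    acc <- q(df$accuracy); rc <- q(df$recall); f1 <- q(df$f1); au <- q(df$auc)
    data.frame(variant = df$variant[1L],
               accuracy_median = acc[2L], accuracy_iqr = acc[3L] - acc[1L],
               recall_median = rc[2L], recall_iqr = rc[3L] - rc[1L],
               f1_median = f1[2L], f1_iqr = f1[3L] - f1[1L],
               auc_median = au[2L], auc_iqr = au[3L] - au[1L],
               n_parameters = df$n_parameters[1L], flops = df$flops[1L],
               n_failed = sum(df$failed))
  })
  list(table = do.call(rbind, c(agg, make.row.names = FALSE)), runs = runs)
}
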