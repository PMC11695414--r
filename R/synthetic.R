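# Seeded generators for paired EEG/video sequences with controllable
# unimodal and cross-modal class signal.  The EEG carrier is a
# class-conditional sinusoid (class k -> frequency f_k on an even grid
# in 4-30 Hz) at amplitude `snr` over unit-variance white noise; the
# video carrier is a bright Gaussian blob moving along a
# class-conditional heading (2*pi*k/|C|) over pixel noise.  In the
# interaction_only regime a bit is planted per modality and the label
# is their XOR, so no single stream is informative.

class_frequencies <- function(n_classes) seq(4, 30, length.out = n_classes)

blob_frame_stack <- function(Tn, h, w, c, heading, snr, sigma_pix = 1,
                             sigma_blob = 1.5) {
  # blob starts at the frame center and heads outward, so the visited
  # positions themselves (not only their time order) are class-conditional
  speed <- max(min(h, w) / 2 - 3, 0.5) / Tn
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  amp <- snr * sigma_pix
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  frames <- array(stats::rnorm(Tn * h * w * c, sd = sigma_pix), c(Tn, h, w, c))
  for (t in seq_len(Tn)) {
    off <- (t - 1) * speed
    px <- cx + off * cos(heading); py <- cy + off * sin(heading)
    blob <- amp * exp(-((xs - px)^2 + (ys - py)^2) / (2 * sigma_blob^2))
    for (ch in seq_len(c)) frames[t, , , ch] <- frames[t, , , ch] + blob
  }
  frames
}

eeg_signal <- function(Tn, d, freq, snr, fs) {
  tt <- (seq_len(Tn) - 1L) / fs
  phases <- stats::runif(d, 0, 2 * pi)
  carrier <- snr * sin(outer(tt, rep(2 * pi * freq, d)) +
                         matrix(phases, Tn, d, byrow = TRUE))
  carrier + matrix(stats::rnorm(Tn * d), Tn, d)
}

#' Generate a synthetic paired EEG/video dataset
#'
#' Produces `n_sequences` triples (EEG, video, labels) with the class
#' signal planted according to `spec$regime` (see [synth_spec()]).
#' Labels are balanced and constant within a sequence; generation is
#' bit-reproducible from `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return an object of class `eegfuse_dataset`: a list of elements
#'   with fields `eeg`, `video`, `labels`, `class`, `subject_id` (and
#'   `bits` in the interaction regime), with the spec attached as
#'   attribute `"spec"`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_sequences; C <- spec$n_classes
  freqs <- class_frequencies(C)
  headings <- 2 * pi * (seq_len(C) - 1L) / C
  with_seed(spec$seed, {
    if (spec$regime == "interaction_only") {
      combos <- expand.grid(a = 0:1, b = 0:1)
      combo_idx <- rep(seq_len(4L), length.out = n)
      a <- combos$a[combo_idx]; b <- combos$b[combo_idx]
      cls <- as.integer(xor(a == 1L, b == 1L))
    } else {
      cls <- rep(seq_len(C) - 1L, length.out = n)
      a <- b <- NULL
    }
    ord <- sample.int(n)
    cls <- cls[ord]
    if (!is.null(a)) { a <- a[ord]; b <- b[ord] }
    n_subjects <- max(2L, n %/% 10L)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      k <- cls[i]
      freq <- switch(spec$regime,
                     eeg_only = freqs[k + 1L],
                     redundant = freqs[k + 1L],
                     video_only = sample(freqs, 1L),
                     interaction_only = freqs[c(1L, C)][a[i] + 1L])
      heading <- switch(spec$regime,
                        video_only = headings[k + 1L],
                        redundant = headings[k + 1L],
                        eeg_only = stats::runif(1, 0, 2 * pi),
                        # orthogonal (not antipodal) headings for the video
                        # bit: with opposite rays the cross-attention
                        # interaction term cancels by symmetry and the XOR
                        # would be undecodable by the fusion it is meant to
                        # exercise (see the methods vignette)
                        interaction_only = (pi / 2) * b[i])
      eeg <- eeg_sequence(eeg_signal(spec$T, spec$d, freq, spec$snr,
                                     spec$sampling_rate),
                          sampling_rate = spec$sampling_rate)
      video <- video_sequence(frames = blob_frame_stack(
        spec$T, spec$h, spec$w, spec$c, heading, spec$snr))
      labels <- label_sequence(rep(k, spec$T), C)
      out[[i]] <- list(eeg = eeg, video = video, labels = labels,
                       class = k, subject_id = ((i - 1L) %% n_subjects) + 1L)
      if (!is.null(a)) out[[i]]$bits <- c(a = a[i], b = b[i])
    }
    structure(out, class = "eegfuse_dataset", spec = spec)
  })
}

#' @export
print.eegfuse_dataset <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<eegfuse_dataset> %d sequences, T=%d, regime=%s\n",
              length(x), sp$T, sp$regime))
  invisible(x)
}

dataset_classes <- function(data) {
  vapply(data, function(s) s$labels$labels[1L], integer(1))
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive, label-stratified and seeded. Within each class,
#' shuffled indices are allocated by largest remainder; fractional seats
#' are carried across classes so global split sizes match the fractions
#' exactly up to rounding (e.g. 70/15/15 at n = 100 gives sizes
#' 70, 15, 15).
#'
#' @param dataset an `eegfuse_dataset` (or a bare integer label vector,
#'   one label per sequence).
#' @param fractions length-3 positive numeric `(train, val, test)`
#'   summing to 1 (within 1e-9).
#' @param seed integer seed for the within-class shuffles.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
holdout_split <- function(dataset, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  labels <- if (inherits(dataset, "eegfuse_dataset")) dataset_classes(dataset)
            else as.integer(dataset)
  if (length(fractions) != 3L || any(fractions <= 0))
    stopf("fractions must be 3 positive numbers", class = "eegfuse_validation_error")
  if (abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must sum to 1", class = "eegfuse_validation_error")
  classes <- sort(unique(labels))
  n_splits <- 3L
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  carry <- numeric(n_splits)
  with_seed(seed, {
    for (k in classes) {
      idx <- which(labels == k)
      if (length(idx) < n_splits)
        stopf("class %s has %d sequences; need at least %d (one per split)",
              k, length(idx), n_splits, class = "eegfuse_validation_error")
      idx <- idx[sample.int(length(idx))]
      ideal <- fractions * length(idx) + carry
      counts <- floor(ideal + 1e-9)
      left <- length(idx) - sum(counts)
      if (left > 0) {
        rem <- ideal - counts
        extra <- order(rem, decreasing = TRUE)[seq_len(left)]  # ties: lower split
        counts[extra] <- counts[extra] + 1
      }
      carry <- ideal - counts
      at <- cumsum(c(0, counts))
      for (s in seq_len(n_splits)) {
        take <- if (counts[s] > 0) idx[(at[s] + 1L):at[s + 1L]] else integer(0)
        parts[[s]] <- c(parts[[s]], take)
      }
    }
  })
  lapply(parts, sort)
}
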