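# Readers and writers.  Three surfaces:
#  * a plain-text dense numeric array container (bit-exact round trip;
#    doubles are serialized with %.17g),
#  * a dataset directory layout (meta.json + eeg/video/labels CSVs,
#    pixel columns flattened with pixel index p = (x-1)*h + y per
#    channel block),
#  * EDF (European Data Format) for EEG channels: 16-bit quantized by
#    the format, so round trips are approximate by construction.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a dense numeric array as plain text
#'
#' Line 1 is a magic/version header, line 2 the dimensions, then the
#' values in column-major order, `%.17g`-formatted so the round trip
#' through [read_dense_array()] is bit-exact.
#'
#' @param x numeric vector, matrix or array (finite).
#' @param path output path.
#' @param meta optional named character vector of metadata lines
#'   (written as `key value`).
#' @return `path`, invisibly.
#' @export
write_dense_array <- function(x, path, meta = NULL) {
  assert_finite(x, "array")
  dm <- dim(x) %||% length(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("eegfuse-dense-array 1", con)
  writeLines(paste("dims", paste(dm, collapse = " ")), con)
  if (!is.null(meta))
    writeLines(paste(names(meta), unname(meta)), con)
  writeLines("data", con)
  vals <- fmt17(as.vector(x))
  idx <- seq(1L, length(vals), by = 8L)
  writeLines(vapply(idx, function(i)
    paste(vals[i:min(i + 7L, length(vals))], collapse = " "), character(1)), con)
  invisible(path)
}

#' Read a dense numeric array written by [write_dense_array()]
#'
#' @param path input path.
#' @return the array (with `dims` restored); metadata lines are attached
#'   as attribute `"meta"`.
#' @export
read_dense_array <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path,
                                class = "eegfuse_io_error")
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "eegfuse-dense-array"))
    stopf("not a dense-array file: %s", path, class = "eegfuse_parse_error")
  if (!startsWith(lines[2L], "dims "))
    stopf("malformed header (missing dims): %s", path,
          class = "eegfuse_parse_error")
  dm <- as.integer(strsplit(lines[2L], " ")[[1L]][-1L])
  data_at <- which(lines == "data")[1L]
  if (is.na(data_at)) stopf("malformed header (missing data): %s", path,
                            class = "eegfuse_parse_error")
  meta <- NULL
  if (data_at > 3L) {
    kv <- strsplit(lines[3:(data_at - 1L)], " ")
    meta <- stats::setNames(vapply(kv, function(p) paste(p[-1L], collapse = " "),
                                   character(1)),
                            vapply(kv, `[`, character(1), 1L))
  }
  vals <- scan(text = lines[(data_at + 1L):length(lines)], quiet = TRUE)
  if (length(vals) != prod(dm))
    stopf("value count %d does not match dims (%s)", length(vals),
          paste(dm, collapse = "x"), class = "eegfuse_parse_error")
  x <- if (length(dm) > 1L) array(vals, dm) else vals
  attr(x, "meta") <- meta
  x
}

#' Read an EEG sequence
#'
#' `dense_array` files map directly to the sample matrix
#' (channels are columns); EDF files map each signal to a column and
#' preserve the header's sampling rate. Non-finite samples are rejected
#' (the documented NaN policy).
#'
#' @param path input file.
#' @param format `"dense_array"` or `"edf"`.
#' @return an [eeg_sequence()].
#' @export
read_eeg <- function(path, format = c("dense_array", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  x <- read_dense_array(path)
  meta <- attr(x, "meta")
  fs <- if (!is.null(meta) && "sampling_rate" %in% names(meta))
    as.numeric(meta[["sampling_rate"]]) else 128
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  attr(x, "meta") <- NULL
  eeg_sequence(x, sampling_rate = fs)
}

#' Write an EEG sequence
#'
#' @param x an [eeg_sequence()].
#' @param path output file.
#' @param format `"dense_array"` (bit-exact) or `"edf"` (16-bit
#'   quantized).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(x, path, format = c("dense_array", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "eeg_sequence"))
  if (format == "edf") return(write_edf(x, path))
  write_dense_array(x$samples, path,
                    meta = c(sampling_rate = fmt17(x$sampling_rate)))
}

# ---- EDF (European Data Format) --------------------------------------

edf_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write EEG channels as an EDF file
#'
#' Minimal EDF writer: one data record holding the whole sequence,
#' samples quantized to 16-bit integers over each channel's physical
#' range. Rejects non-finite samples.
#'
#' @param x an [eeg_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  stopifnot(inherits(x, "eeg_sequence"))
  S <- x$samples
  ns <- ncol(S); Tn <- nrow(S)
  assert_finite(S, "EEG samples")
  pmin_ <- apply(S, 2L, min); pmax_ <- apply(S, 2L, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768; dmax <- 32767
  header <- paste0(
    edf_field("0", 8L), edf_field("eegfuse", 80L), edf_field("synthetic", 80L),
    edf_field("01.01.26", 8L), edf_field("00.00.00", 8L),
    edf_field(256L * (1L + ns), 8L), edf_field("", 44L),
    edf_field(1L, 8L), edf_field(fmt_num8(Tn / x$sampling_rate), 8L),
    edf_field(ns, 4L))
  sig <- paste0(
    paste(vapply(seq_len(ns), function(i) edf_field(sprintf("EEG ch%d", i), 16L),
                 character(1)), collapse = ""),
    strrep(edf_field("", 80L), ns),
    strrep(edf_field("uV", 8L), ns),
    paste(vapply(pmin_, function(v) edf_field(fmt_num8(v), 8L), character(1)),
          collapse = ""),
    paste(vapply(pmax_, function(v) edf_field(fmt_num8(v), 8L), character(1)),
          collapse = ""),
    strrep(edf_field(dmin, 8L), ns), strrep(edf_field(dmax, 8L), ns),
    strrep(edf_field("", 80L), ns),
    strrep(edf_field(Tn, 8L), ns), strrep(edf_field("", 32L), ns))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((S[, i] - pmin_[i]) / (pmax_[i] - pmin_[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# EDF numeric fields are 8 ASCII chars; keep as many significant digits
# as fit.
fmt_num8 <- function(v) {
  for (digits in 6:0) {
    s <- formatC(v, digits = digits, format = "g", width = 1)
    if (nchar(s) <= 8L) return(s)
  }
  substr(formatC(v, format = "g"), 1L, 8L)
}

#' Read an EDF file into an EEG sequence
#'
#' @param path EDF file path.
#' @return an [eeg_sequence()]; channels become columns, the sampling
#'   rate is reconstructed from the record duration.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path,
                                class = "eegfuse_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L)
    stopf("malformed EDF header (truncated): %s", path,
          class = "eegfuse_parse_error")
  grab <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_rec <- suppressWarnings(as.integer(grab(hdr, 237L, 8L)))
  dur <- suppressWarnings(as.numeric(grab(hdr, 245L, 8L)))
  ns <- suppressWarnings(as.integer(grab(hdr, 253L, 4L)))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L)
    stopf("malformed EDF header (signal/record counts): %s", path,
          class = "eegfuse_parse_error")
  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  # signal header block: each field is stored for all signals in a run;
  # byte offsets of the runs are label 0 (16), transducer 16*ns (80),
  # phys dim 96*ns (8), phys min 104*ns, phys max 112*ns,
  # dig min 120*ns, dig max 128*ns, prefilter 136*ns (80),
  # samples/record 216*ns (8)
  at <- function(off, width) vapply(seq_len(ns), function(i)
    grab(sig, off * ns + (i - 1L) * width + 1L, width), character(1))
  pmin_ <- as.numeric(at(104L, 8L))
  pmax_ <- as.numeric(at(112L, 8L))
  dmin <- as.numeric(at(120L, 8L))
  dmax <- as.numeric(at(128L, 8L))
  spr <- as.integer(at(216L, 8L))
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)))
    stopf("malformed EDF signal headers: %s", path,
          class = "eegfuse_parse_error")
  if (length(unique(spr)) != 1L)
    stopf("channel-length mismatch across EDF signals: %s", path,
          class = "eegfuse_parse_error")
  Tn <- spr[1L] * n_rec
  out <- matrix(NA_real_, Tn, ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[i], size = 2L, endian = "little",
                     signed = TRUE)
      if (length(raw) != spr[i])
        stopf("truncated EDF data record: %s", path,
              class = "eegfuse_parse_error")
      phys <- pmin_[i] + (raw - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
      out[((r - 1L) * spr[i] + 1L):(r * spr[i]), i] <- phys
    }
  }
  if (!all(is.finite(out)))
    stopf("EDF contains non-finite samples after scaling (NaN policy: reject)",
          class = "eegfuse_validation_error")
  fs <- if (!is.na(dur) && dur > 0) spr[1L] / dur else 128
  eeg_sequence(out, sampling_rate = fs)
}

# ---- dataset directory layout ----------------------------------------

#' Write a dataset directory
#'
#' Layout: `meta.json` (geometry, classes, regime, seed),
#' `eeg.csv` (`seq, step, ch1..chd`), `video.csv`
#' (`seq, step, px1..px(h*w*c)`; pixel index `p = (x-1)*h + y`, channel
#' blocks concatenated), `labels.csv` (`seq, step, label`). Values are
#' `%.17g`-formatted for exact round trips.
#'
#' @param data an `eegfuse_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- attr(data, "spec")
  jsonlite::write_json(
    list(n_sequences = length(data), T = sp$T, d = sp$d, h = sp$h, w = sp$w,
         c = sp$c, n_classes = sp$n_classes, regime = sp$regime, snr = sp$snr,
         sampling_rate = sp$sampling_rate, seed = sp$seed,
         label_base = 0L, format_version = 1L),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  Tn <- sp$T
  eeg <- do.call(rbind, lapply(seq_along(data), function(i)
    cbind(i, seq_len(Tn), data[[i]]$eeg$samples)))
  vid <- do.call(rbind, lapply(seq_along(data), function(i) {
    fr <- data[[i]]$video$frames
    cbind(i, seq_len(Tn), matrix(fr, nrow = Tn))
  }))
  lab <- do.call(rbind, lapply(seq_along(data), function(i)
    cbind(i, seq_len(Tn), data[[i]]$labels$labels)))
  wr <- function(m, names1, path) {
    df <- data.table::as.data.table(m)
    data.table::setnames(df, c("seq", "step", names1))
    num <- names(df)[-(1:2)]
    for (cn in num) data.table::set(df, j = cn, value = fmt17(df[[cn]]))
    data.table::fwrite(df, path)
  }
  wr(eeg, paste0("ch", seq_len(sp$d)), file.path(dir, "eeg.csv"))
  wr(vid, paste0("px", seq_len(sp$h * sp$w * sp$c)), file.path(dir, "video.csv"))
  labdf <- data.table::data.table(seq = lab[, 1L], step = lab[, 2L],
                                  label = as.integer(lab[, 3L]))
  data.table::fwrite(labdf, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return an `eegfuse_dataset`.
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stopf("missing meta.json in %s", dir, class = "eegfuse_io_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  eeg <- data.table::fread(file.path(dir, "eeg.csv"))
  vid <- data.table::fread(file.path(dir, "video.csv"))
  lab <- data.table::fread(file.path(dir, "labels.csv"))
  n <- meta$n_sequences; Tn <- meta$T
  spec <- synth_spec(n_sequences = n, T = Tn, d = meta$d, h = meta$h,
                     w = meta$w, c = meta$c, n_classes = meta$n_classes,
                     regime = meta$regime, snr = meta$snr,
                     sampling_rate = meta$sampling_rate, seed = meta$seed)
  base <- meta$label_base %||% 0L
  Em <- unname(as.matrix(eeg[, -(1:2)])); Vm <- unname(as.matrix(vid[, -(1:2)]))
  Lv <- lab$label - base
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * Tn + 1L):(i * Tn)
    frames <- array(Vm[rows, ], c(Tn, meta$h, meta$w, meta$c))
    labels <- label_sequence(Lv[rows], meta$n_classes)
    out[[i]] <- list(eeg = eeg_sequence(Em[rows, , drop = FALSE],
                                        sampling_rate = meta$sampling_rate),
                     video = video_sequence(frames = frames),
                     labels = labels, class = labels$labels[1L],
                     subject_id = ((i - 1L) %% max(2L, n %/% 10L)) + 1L)
  }
  structure(out, class = "eegfuse_dataset", spec = spec)
}

# ---- checkpoints and manifests ---------------------------------------

#' Save a model checkpoint
#'
#' One JSON file: the configuration and variant as plain structured
#' text, each parameter array as its dimensions plus the base64-encoded
#' IEEE-754 doubles, so [load_checkpoint()] round-trips bit-exactly.
#'
#' @param model an `eegfuse_model`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "eegfuse_model"))
  params <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         data = jsonlite::base64_enc(writeBin(as.numeric(p), raw(),
                                              size = 8L, endian = "little")))
  })
  jsonlite::write_json(
    list(package = "eegfuse",
         version = as.character(utils::packageVersion("eegfuse")),
         variant = model$variant,
         config = unclass(model$config),
         params = params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return an `eegfuse_model`, bit-identical to the one saved.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path,
                                class = "eegfuse_io_error")
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$package, "eegfuse"))
    stopf("not an eegfuse checkpoint: %s", path, class = "eegfuse_parse_error")
  cfgl <- ck$config
  cfg <- model_config(d = cfgl$d, h = cfgl$h, w = cfgl$w, c = cfgl$c,
                      h_v = cfgl$h_v, d_h = cfgl$d_h, d_f = cfgl$d_f,
                      n_classes = cfgl$n_classes, conv_kernel = cfgl$conv_kernel,
                      dropout_p = cfgl$dropout_p,
                      use_knn_attention = cfgl$use_knn_attention,
                      knn_k = cfgl$knn_k,
                      use_positional_encoding = cfgl$use_positional_encoding,
                      use_spatial_positions = cfgl$use_spatial_positions,
                      activation = cfgl$activation, max_T = cfgl$max_T,
                      scale_attention = cfgl$scale_attention,
                      head_mode = cfgl$head_mode)
  params <- lapply(ck$params, function(p) {
    v <- readBin(jsonlite::base64_dec(p$data), numeric(),
                 n = prod(unlist(p$dim)), size = 8L, endian = "little")
    dm <- unlist(p$dim)
    if (length(dm) == 2L) matrix(v, dm[1], dm[2]) else v
  })
  structure(list(config = cfg, variant = ck$variant, params = params),
            class = "eegfuse_model")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte: the
#' effective configuration snapshot, the seed, MD5 content hashes of the
#' input files, the package version and a timestamp.
#'
#' @param path output JSON path.
#' @param config named list: the effective configuration.
#' @param seed integer seed of the run.
#' @param input_files character vector of input paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, input_files = character(0)) {
  hashes <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  jsonlite::write_json(
    list(config = config, seed = seed, input_hashes = hashes,
         package_version = as.character(utils::packageVersion("eegfuse")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
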