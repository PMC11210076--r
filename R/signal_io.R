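# Recording containers, probe layouts, and readers/writers for the TSV
# recording dialect and minimal EDF.

GROUP_LABELS <- c("P", "S", "PC", "SC", "CS", "SYNTH")

infer_modality <- function(label) {
  ifelse(grepl("^N[0-9]+$", label), "FNIRS",
    ifelse(toupper(label) == "ECG", "ECG",
      ifelse(toupper(label) == "RESP", "RESP",
        ifelse(grepl("^(IHR|IRR|RATE)", toupper(label)), "RATE", "EEG"))))
}

default_units <- function(modality) {
  c(EEG = "uV", FNIRS = "umol/mL", ECG = "arbitrary",
    RESP = "arbitrary", RATE = "Hz")[modality]
}

#' Construct a multichannel recording
#'
#' The central container: uniformly sampled channels of one subject,
#' all sharing one sampling rate and length, plus subject and group
#' metadata.
#'
#' @param channels A tibble with columns `label`, `samples`
#'   (list-column of numeric vectors) and optionally `modality`,
#'   `units`; or a named list of numeric vectors.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param group_label One of `"P"`, `"S"`, `"PC"`, `"SC"`, `"CS"`,
#'   `"SYNTH"`.
#' @param t0 Start offset in seconds.
#' @return A `nv_recording` object.
#' @export
nv_recording <- function(channels, fs, subject_id = "subject",
                         group_label = "SYNTH", t0 = 0) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (!group_label %in% GROUP_LABELS) {
    stop_nvcoh(sprintf("Unknown group label '%s'.", group_label),
               "nvcoh_validation_error")
  }
  if (is.list(channels) && !is.data.frame(channels)) {
    channels <- tibble(label = names(channels),
                       samples = unname(channels))
  }
  stopifnot(is.data.frame(channels),
            all(c("label", "samples") %in% names(channels)))
  if (nrow(channels) == 0L) {
    stop_nvcoh("A recording needs at least one channel.",
               "nvcoh_validation_error")
  }
  if (!"modality" %in% names(channels)) {
    channels$modality <- infer_modality(channels$label)
  }
  if (!"units" %in% names(channels)) {
    channels$units <- unname(default_units(channels$modality))
  }
  lens <- vapply(channels$samples, length, numeric(1))
  if (length(unique(lens)) != 1L) {
    stop_nvcoh("All channels must have the same length.",
               "nvcoh_validation_error")
  }
  if (lens[1] < 2L) {
    stop_nvcoh("Channels must hold at least two samples.",
               "nvcoh_validation_error")
  }
  for (s in channels$samples) assert_numeric_series(s, "samples")
  structure(list(subject_id = subject_id, group_label = group_label,
                 fs = fs, t0 = t0,
                 channels = as_tibble(channels[c("label", "modality",
                                                 "units", "samples")])),
            class = "nv_recording")
}

#' @export
print.nv_recording <- function(x, ...) {
  cat(sprintf("<nv_recording> subject %s (%s): %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group_label, nrow(x$channels),
              length(x$channels$samples[[1]]), x$fs))
  print(x$channels[c("label", "modality", "units")], n = 5)
  invisible(x)
}

#' Extract one channel's samples from a recording
#'
#' @param rec A `nv_recording`.
#' @param label Channel label.
#' @return Numeric vector of samples.
#' @export
channel_samples <- function(rec, label) {
  i <- match(label, rec$channels$label)
  if (is.na(i)) {
    stop_nvcoh(sprintf("No channel labelled '%s'.", label),
               "nvcoh_validation_error")
  }
  rec$channels$samples[[i]]
}

#' Probe layout of the fNIRS/EEG montage
#'
#' The default layout is the 16-electrode EEG montage (Fp1..O2) with 11
#' fNIRS probes (N1..N11). The published co-location map covers
#' N3 (right occipital, over O2) and N5 (left occipital, over O1); the
#' remaining co-locations are user-configurable.
#'
#' @param eeg_labels,fnirs_labels Ordered label vectors.
#' @param colocation Named character vector mapping fNIRS labels to EEG
#'   labels.
#' @return A `nv_layout` object.
#' @export
probe_layout <- function(
    eeg_labels = c("Fp1", "Fp2", "F3", "F4", "T7", "C3", "Cz", "C4",
                   "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    fnirs_labels = paste0("N", 1:11),
    colocation = c(N3 = "O2", N5 = "O1")) {
  stopifnot(!anyDuplicated(eeg_labels), !anyDuplicated(fnirs_labels))
  if (length(colocation) &&
      (!all(names(colocation) %in% fnirs_labels) ||
       !all(colocation %in% eeg_labels))) {
    stop_nvcoh("Co-location map references unknown labels.",
               "nvcoh_validation_error")
  }
  structure(list(eeg = eeg_labels, fnirs = fnirs_labels,
                 colocation = colocation),
            class = "nv_layout")
}

#' @export
print.nv_layout <- function(x, ...) {
  cat(sprintf("<nv_layout> %d EEG electrodes, %d fNIRS probes, %d co-located\n",
              length(x$eeg), length(x$fnirs), length(x$colocation)))
  invisible(x)
}

#' Read or write a probe layout as JSON
#'
#' @param path File path.
#' @return `read_layout()` returns a `nv_layout`.
#' @export
read_layout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  probe_layout(doc$eeg, doc$fnirs, unlist(doc$colocation) %||% character())
}

#' @rdname read_layout
#' @param layout A `nv_layout`.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(eeg = layout$eeg, fnirs = layout$fnirs,
                            colocation = as.list(layout$colocation)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Enumerate analysis channel pairs
#'
#' Unordered unique pairs in deterministic (layout) order: all 55
#' fNIRS–fNIRS pairs, 120 EEG–EEG pairs, or 176 fNIRS–EEG combinations
#' for the default montage.
#'
#' @param layout A `nv_layout`.
#' @param mode One of `"fnirs_fnirs"`, `"eeg_eeg"`, `"fnirs_eeg"`.
#' @return A tibble with columns `a`, `b`.
#' @export
enumerate_pairs <- function(layout = probe_layout(),
                            mode = c("fnirs_fnirs", "eeg_eeg", "fnirs_eeg")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "nv_layout"))
  if (mode == "fnirs_eeg") {
    grid <- expand.grid(b = layout$eeg, a = layout$fnirs,
                        stringsAsFactors = FALSE)
    return(tibble(a = grid$a, b = grid$b))
  }
  labs <- if (mode == "fnirs_fnirs") layout$fnirs else layout$eeg
  idx <- utils::combn(length(labs), 2)
  tibble(a = labs[idx[1, ]], b = labs[idx[2, ]])
}

# ---- TSV recording dialect ------------------------------------------------
# Plain text, diff-friendly: "#key=value" metadata lines (fs mandatory),
# optional "#units=" / "#modality=" tab-separated lines aligned with the
# header, then a tab-separated header of channel labels and the samples.

read_recording_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#", "", ln)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  if (is.null(meta$fs)) {
    stop_nvcoh("TSV recording lacks a '#fs=' metadata line.",
               "nvcoh_io_error")
  }
  body_start <- if (length(meta_idx)) max(meta_idx) + 1L else 1L
  header <- strsplit(lines[body_start], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(text = lines[-seq_len(body_start)], sep = "\t",
                           colClasses = "numeric", col.names = header,
                           check.names = FALSE)
  ch <- tibble(label = header,
               samples = lapply(header, function(h) dat[[h]]))
  if (!is.null(meta$modality)) {
    ch$modality <- strsplit(meta$modality, "\t", fixed = TRUE)[[1]]
  }
  if (!is.null(meta$units)) {
    ch$units <- strsplit(meta$units, "\t", fixed = TRUE)[[1]]
  }
  nv_recording(ch, fs = as.numeric(meta$fs),
               subject_id = meta$subject %||% "subject",
               group_label = meta$group %||% "SYNTH",
               t0 = as.numeric(meta$t0 %||% "0"))
}

write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#fs=%.10g", rec$fs),
    sprintf("#subject=%s", rec$subject_id),
    sprintf("#group=%s", rec$group_label),
    sprintf("#t0=%.10g", rec$t0),
    sprintf("#modality=%s", paste(rec$channels$modality, collapse = "\t")),
    sprintf("#units=%s", paste(rec$channels$units, collapse = "\t")),
    paste(rec$channels$label, collapse = "\t")
  ), con)
  mat <- do.call(cbind, rec$channels$samples)
  utils::write.table(format(mat, digits = 10, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- minimal EDF ----------------------------------------------------------
# Single-data-record EDF: ASCII header blocks per the format, samples as
# little-endian int16 scaled by per-channel physical min/max. 16-bit
# quantization bounds round-trip accuracy at ~range/2^16 per channel.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$channels)
  n <- length(rec$channels$samples[[1]])
  duration <- n / rec$fs
  pmin_ <- vapply(rec$channels$samples, min, numeric(1))
  pmax_ <- vapply(rec$channels$samples, max, numeric(1))
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field(paste0("group=", rec$group_label), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("", 44),
    pad_field(1, 8),
    pad_field(format(duration, digits = 7), 8),
    pad_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(pad_field(rec$channels$label, 16), collapse = ""),
    paste(pad_field(rec$channels$modality, 80), collapse = ""),
    paste(pad_field(rec$channels$units, 8), collapse = ""),
    paste(pad_field(format(pmin_, digits = 7), 8), collapse = ""),
    paste(pad_field(format(pmax_, digits = 7), 8), collapse = ""),
    paste(pad_field(rep(-32768, ns), 8), collapse = ""),
    paste(pad_field(rep(32767, ns), 8), collapse = ""),
    paste(pad_field(rep("", ns), 80), collapse = ""),
    paste(pad_field(rep(n, ns), 8), collapse = ""),
    paste(pad_field(rep("", ns), 32), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (i in seq_len(ns)) {
    x <- rec$channels$samples[[i]]
    dig <- round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8)                      # version
  subject <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8)               # date, time
  rd(8)                      # header bytes
  rd(44)                     # reserved
  n_rec <- as.integer(rd(8))
  rd(8)                      # record duration
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  transducer <- vapply(seq_len(ns), function(i) rd(80), character(1))
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))  # prefilter
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))  # reserved
  dur <- attr(read_edf_duration(path), "duration")
  samples <- vector("list", ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) *
        (pmax_[i] - pmin_[i])
      samples[[i]] <- c(samples[[i]], phys)
    }
  }
  fs <- nsamp[1] / dur
  known <- transducer %in% c("EEG", "FNIRS", "ECG", "RESP", "RATE")
  if (!all(known)) {
    warn("EDF channels without a stored modality default to EEG.")
  }
  group <- sub("^group=", "", recinfo)
  if (!group %in% GROUP_LABELS) group <- "SYNTH"
  nv_recording(
    tibble(label = labels,
           modality = ifelse(known, transducer, infer_modality(labels)),
           units = units, samples = samples),
    fs = fs, subject_id = subject, group_label = group)
}

# Record duration field sits at byte offset 244 (8 ASCII chars).
read_edf_duration <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 244)
  structure(path, duration = as.numeric(readChar(con, 8, useBytes = TRUE)))
}

#' Read a recording from disk
#'
#' Supports the package's tab-separated dialect (metadata lines
#' `#fs=...` etc., a header of channel labels, then samples) and
#' minimal EDF. Channel modalities are taken from file metadata when
#' present, otherwise inferred from the label (N* = fNIRS, ECG/RESP
#' literal, IHR/IRR = rate, anything else EEG).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"edf"`.
#' @return A `nv_recording`.
#' @export
read_recording <- function(path, format = c("auto", "tsv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_nvcoh(sprintf("File '%s' does not exist.", path), "nvcoh_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  }
  if (format == "edf") read_recording_edf(path) else read_recording_tsv(path)
}

#' Write a recording to disk
#'
#' The TSV dialect round-trips samples to full double precision; EDF is
#' quantized to 16 bits over each channel's physical range
#' (relative error ~1.5e-5 of the range).
#'
#' @param rec A `nv_recording`.
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "tsv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "nv_recording"))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  }
  if (format == "edf") write_recording_edf(rec, path)
  else write_recording_tsv(rec, path)
}
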