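# Preprocessing: segment extraction, polynomial detrending, zero-phase
# Butterworth bandpass, moving-average downsampling.

#' Analysis sampling-rate presets
#'
#' Target rates for each analysis family: 31.25 Hz for fNIRS–EEG
#' coherence (the fNIRS acquisition rate), 20 Hz for sub-4 Hz EEG–EEG
#' and fNIRS–rate/respiration coherence, 142 Hz for EEG above the delta
#' band, and 100 Hz for ECG/respiration before rate extraction.
#'
#' @return Named numeric vector of rates in Hz.
#' @export
analysis_rates <- function() {
  c(fnirs_eeg = 31.25, slow = 20, eeg_fast = 142, rate_extraction = 100)
}

#' Extract a continuous segment from a recording
#'
#' Cuts all channels to the same `[start, start + length)` window.
#' The default analysis segment is the first 1200 s (20 min) of a
#' recording.
#'
#' @param rec A `nv_recording`.
#' @param start Segment start in seconds from the beginning.
#' @param length Segment length in seconds.
#' @return A `nv_recording` with the same channels and rate.
#' @export
extract_segment <- function(rec, start = 0, length = 1200) {
  stopifnot(inherits(rec, "nv_recording"))
  n <- base::length(rec$channels$samples[[1]])
  i0 <- floor(start * rec$fs) + 1
  i1 <- i0 + floor(length * rec$fs) - 1
  if (start < 0 || i1 > n) {
    stop_nvcoh("Requested window exceeds the recording duration.",
               "nvcoh_range_error")
  }
  rec$channels$samples <- lapply(rec$channels$samples, function(x) x[i0:i1])
  rec$t0 <- rec$t0 + start
  rec
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial fit of the given order over
#' the full segment, removing drifts slower than the frequencies of
#' interest. Order 3 is the pipeline default; order 0 subtracts the
#' mean.
#'
#' @param x Real series.
#' @param fs Sampling rate in Hz (sets the time axis; does not affect
#'   the residual).
#' @param order Polynomial order (>= 0).
#' @return The detrended series.
#' @export
detrend_poly <- function(x, fs = 1, order = 3) {
  assert_numeric_series(x, "x", min_length = order + 2)
  if (order < 0 || order != round(order)) {
    stop_nvcoh("`order` must be a nonnegative integer.",
               "nvcoh_validation_error")
  }
  if (order == 0) return(x - mean(x))
  t <- seq_along(x) / fs
  fit <- stats::lm.fit(cbind(1, stats::poly(t, order)), x)
  unname(fit$residuals)
}

# One zero-phase second-order Butterworth stage with reflect padding.
filtfilt_padded <- function(x, filt, npad) {
  n <- length(x)
  npad <- min(npad, n - 1)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filtfilt(filt, xp)
  y[npad + seq_len(n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Cascade of a second-order Butterworth high-pass at `lo` and low-pass
#' at `hi`, each applied forward and backward (zero phase shift, which
#' downstream phase-coherence estimates depend on; effective magnitude
#' response is the squared Butterworth response, ~24 dB/octave per
#' stage). Edges are reflect-padded before filtering to suppress
#' transients at the very low cut-off frequencies used here.
#'
#' @param x Real series.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Passband edges in Hz, `0 < lo < hi < fs/2`. The default
#'   0.007–4 Hz is the cardiovascular analysis band; 4–48 Hz is used
#'   for EEG above delta.
#' @return The filtered series.
#' @export
bandpass <- function(x, fs, lo = 0.007, hi = 4) {
  assert_numeric_series(x)
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (lo <= 0 || lo >= hi || hi >= fs / 2) {
    stop_nvcoh("Need 0 < lo < hi < fs/2.", "nvcoh_validation_error")
  }
  hp <- signal::butter(2, lo / (fs / 2), type = "high")
  lp <- signal::butter(2, hi / (fs / 2), type = "low")
  npad <- min(length(x) - 1, ceiling(3 / lo * fs))
  y <- filtfilt_padded(x, hp, npad)
  filtfilt_padded(y, lp, npad)
}

#' Moving-average downsampling
#'
#' Smooths with a centred moving average of width ~`fs_in / fs_out`
#' samples (suppressing energy above the new Nyquist frequency without
#' phase distortion) and resamples by linear interpolation onto the
#' uniform `fs_out` grid. Handles non-integer rate ratios such as
#' 1000 to 142 Hz.
#'
#' @param x Real series.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return The downsampled series, length `floor(length(x) * fs_out / fs_in)`.
#' @export
downsample_moving_average <- function(x, fs_in, fs_out) {
  assert_numeric_series(x)
  if (fs_out > fs_in) {
    stop_nvcoh("`fs_out` must not exceed `fs_in`.", "nvcoh_validation_error")
  }
  n <- length(x)
  m <- floor(n * fs_out / fs_in)
  if (fs_out == fs_in) return(x[seq_len(m)])
  w <- max(2L, round(fs_in / fs_out))
  kern <- rep(1 / w, w)
  xe <- c(rep(x[1], w), x, rep(x[n], w))
  sm <- stats::filter(xe, kern, sides = 2)
  sm <- as.numeric(sm)[w + seq_len(n)]
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- (seq_len(m) - 1) / fs_out
  approx(t_in, sm, xout = t_out, rule = 2)$y
}

#' Preprocess one channel for analysis
#'
#' The standard chain: polynomial detrend, zero-phase bandpass,
#' moving-average downsample. Composition preserves the phase of
#' in-band oscillations, which is the property the coherence stage
#' relies on.
#'
#' @param x Real series.
#' @param fs Sampling rate in Hz.
#' @param detrend_order Polynomial order (default 3).
#' @param band `c(lo, hi)` passband in Hz (default 0.007–4).
#' @param target_fs Output rate in Hz, or `NULL` to keep `fs`.
#' @return The preprocessed series.
#' @export
preprocess_channel <- function(x, fs, detrend_order = 3,
                               band = c(0.007, 4), target_fs = NULL) {
  y <- detrend_poly(x, fs, detrend_order)
  y <- bandpass(y, fs, band[1], band[2])
  if (!is.null(target_fs) && target_fs < fs) {
    y <- downsample_moving_average(y, fs, target_fs)
  }
  y
}
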