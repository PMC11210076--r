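# Wavelet phase coherence, time-localized coherence, inter-subject
# surrogate thresholds and effective coherence.

check_tfr_pair <- function(tfr1, tfr2) {
  if (!inherits(tfr1, "nv_tfr") || !inherits(tfr2, "nv_tfr")) {
    stop_nvcoh("Both inputs must be nv_tfr objects.", "nvcoh_usage_error")
  }
  if (!isTRUE(all.equal(tfr1$grid$values, tfr2$grid$values)) ||
      tfr1$fs != tfr2$fs || nrow(tfr1$coef) != nrow(tfr2$coef)) {
    stop_nvcoh("The two transforms must share grid, sampling rate and span.",
               "nvcoh_usage_error")
  }
  invisible(TRUE)
}

# Unit cross-phasor field z = exp(i * (phi1 - phi2)), NA where either
# coefficient vanishes.
cross_phasor <- function(tfr1, tfr2) {
  z <- tfr1$coef * Conj(tfr2$coef)
  m <- Mod(z)
  z <- z / ifelse(m > 0, m, 1)
  z[m == 0] <- NA_complex_
  z
}

# Cached representation for fast repeated coherence: per-frequency unit
# phasors with cone-of-influence samples zeroed (the COI is a contiguous
# margin per frequency, so pairwise valid counts follow from the
# margins alone).
phasor_field <- function(tfr) {
  stopifnot(inherits(tfr, "nv_tfr"))
  z <- tfr$coef
  m <- Mod(z)
  z <- z / ifelse(m > 0, m, 1)
  z[m == 0] <- 0
  n <- nrow(z)
  for (j in seq_len(ncol(z))) {
    cm <- tfr$coi_samples[j]
    if (cm > 0) {
      top <- seq_len(min(cm, n))
      z[top, j] <- 0
      z[n + 1 - top, j] <- 0
    }
  }
  list(z = z, coi = pmin(tfr$coi_samples, floor(n / 2)), n = n,
       frequency = tfr$grid$values)
}

# Raw coherence between two cached phasor fields.
phasor_coherence <- function(pf1, pf2) {
  nv <- pmax(pf1$n - 2 * pmax(pf1$coi, pf2$coi), 0)
  zs <- colSums(pf1$z * Conj(pf2$z))
  ifelse(nv > 0, pmin(Mod(zs) / nv, 1), NA_real_)
}

#' Wavelet phase coherence between two time series
#'
#' At each frequency, measures how constant the phase difference between
#' the two transforms is over time: the magnitude of the time-averaged
#' unit phasor of the phase difference. 1 means a perfectly constant
#' phase difference; independent signals give small positive values
#' whose magnitude depends on the number of effective cycles (hence the
#' surrogate thresholds, see [surrogate_threshold()]). Phase coherence
#' is by construction independent of the signals' amplitudes. Only
#' samples outside both cones of influence enter the average.
#'
#' @param tfr1,tfr2 `nv_tfr` objects on the same grid, rate and span.
#' @return A `nv_coherence`: tibble with columns `frequency`, `raw`
#'   (coherence in `[0, 1]`), `phase_diff` (circular mean of
#'   `phi1 - phi2` in `(-pi, pi]`; positive means the first signal
#'   leads), `n_valid`.
#' @export
wavelet_phase_coherence <- function(tfr1, tfr2) {
  check_tfr_pair(tfr1, tfr2)
  pf1 <- phasor_field(tfr1)
  pf2 <- phasor_field(tfr2)
  nv <- pmax(pf1$n - 2 * pmax(pf1$coi, pf2$coi), 0)
  zbar <- colSums(pf1$z * Conj(pf2$z)) / pmax(nv, 1)
  raw <- ifelse(nv > 0, Mod(zbar), NA_real_)
  pd <- ifelse(nv > 0, Arg(zbar), NA_real_)
  pd[!is.na(pd) & pd <= -pi] <- pi
  out <- tibble(frequency = tfr1$grid$values, raw = pmin(raw, 1),
                phase_diff = pd, n_valid = as.integer(nv))
  structure(out, class = c("nv_coherence", class(out)), fs = tfr1$fs)
}

#' Time-localized wavelet phase coherence
#'
#' Phase coherence computed in a sliding window whose length is a fixed
#' number of oscillation cycles at each frequency, giving a time x
#' frequency map of transient phase locking. Short windows bias
#' coherence upwards, so the window is expressed in cycles (default 10)
#' rather than seconds.
#'
#' @param tfr1,tfr2 `nv_tfr` objects on the same grid, rate and span.
#' @param window_cycles Window length in oscillation periods.
#' @return A `nv_tlwpc` object: list with `map` (time x frequency
#'   matrix in `[0, 1]`, `NA` where the window does not fit or touches
#'   the cone of influence), `frequency`, `time`, `fs`. Frequencies
#'   whose window exceeds the record are all-`NA`.
#' @export
time_localized_wpc <- function(tfr1, tfr2, window_cycles = 10) {
  check_tfr_pair(tfr1, tfr2)
  assert_scalar_num(window_cycles, "window_cycles", positive = TRUE)
  z <- cross_phasor(tfr1, tfr2)
  valid <- coi_mask(tfr1) & coi_mask(tfr2) & !is.na(z)
  z[!valid] <- 0
  n <- nrow(z)
  fs <- tfr1$fs
  freqs <- tfr1$grid$values
  map <- matrix(NA_real_, n, length(freqs))
  for (j in seq_along(freqs)) {
    w <- round(window_cycles / freqs[j] * fs)
    if (w < 2 || w > n) next
    cz <- c(0, cumsum(z[, j]))
    cv <- c(0, cumsum(valid[, j]))
    starts <- seq_len(n - w + 1)
    sums <- cz[starts + w] - cz[starts]
    cnts <- cv[starts + w] - cv[starts]
    vals <- ifelse(cnts >= 0.9 * w, Mod(sums) / pmax(cnts, 1), NA_real_)
    centre <- starts + floor(w / 2) - 1
    map[centre, j] <- pmin(vals, 1)
  }
  structure(list(map = map, frequency = freqs,
                 time = (seq_len(n) - 1) / fs, fs = fs,
                 window_cycles = window_cycles),
            class = "nv_tlwpc")
}

#' @export
print.nv_tlwpc <- function(x, ...) {
  cat(sprintf("<nv_tlwpc> %d samples x %d frequencies, window %g cycles\n",
              nrow(x$map), ncol(x$map), x$window_cycles))
  invisible(x)
}

#' Inter-subject surrogate coherence threshold
#'
#' Two finite records always show non-zero apparent coherence,
#' especially at low frequencies where few cycles fit the record. To
#' calibrate this, coherence is computed between channel `a` of one
#' subject and channel `b` of a *different* subject — pairings with no
#' physical link — and the per-frequency threshold is a percentile
#' (default 95th, nearest rank) of that surrogate ensemble. Surrogate
#' pairings are ordered cross-subject pairs drawn uniformly at random
#' without repetition.
#'
#' @param cohort A list of recordings (see [read_recording()] /
#'   [gen_cohort()]), or a list of precomputed `nv_tfr` objects per
#'   subject when `channel_a`/`channel_b` are `NULL`.
#' @param channel_a,channel_b Channel labels to pair across subjects.
#' @param n_surrogates Number of surrogate pairings (default 176).
#' @param percentile Threshold percentile (default 95; needs
#'   `n_surrogates >= 19` for a meaningful 95th percentile).
#' @param seed Integer seed for the pairing draw.
#' @param tf_params List controlling the transform applied to every
#'   channel: `grid`, `wavelet`, `resolution`, and optionally
#'   `prepare`, a function `f(x, fs)` applied to each raw channel
#'   before the transform (use this to preprocess identically).
#' @return A `nv_surrogate` tibble with columns `frequency`,
#'   `threshold`, carrying the full surrogate ensemble (matrix
#'   n_surrogates x n_freq), the pairing table and the seed as
#'   attributes.
#' @export
surrogate_threshold <- function(cohort, channel_a = NULL, channel_b = NULL,
                                n_surrogates = 176, percentile = 95,
                                seed = 1L,
                                tf_params = list()) {
  if (length(cohort) < 2L) {
    stop_nvcoh("Need at least two subjects for inter-subject surrogates.",
               "nvcoh_validation_error")
  }
  if (n_surrogates < 19 && percentile >= 95) {
    stop_nvcoh("A 95th percentile needs at least 19 surrogates.",
               "nvcoh_validation_error")
  }
  if (inherits(cohort[[1]], "nv_tfr")) {
    tfrs_a <- cohort
    tfrs_b <- cohort
  } else {
    grid <- tf_params$grid %||% make_log_grid()
    wavelet <- tf_params$wavelet %||% "morlet"
    resolution <- tf_params$resolution %||% 1
    prepare <- tf_params$prepare %||% function(x, fs) x
    len <- min(vapply(cohort, function(r) length(r$channels$samples[[1]]),
                      numeric(1)))
    get_tfr <- function(rec, label) {
      x <- channel_samples(rec, label)[seq_len(len)]
      wavelet_transform(prepare(x, rec$fs), rec$fs, grid,
                        wavelet = wavelet, resolution = resolution)
    }
    tfrs_a <- lapply(cohort, get_tfr, label = channel_a)
    tfrs_b <- if (identical(channel_a, channel_b)) tfrs_a else {
      lapply(cohort, get_tfr, label = channel_b)
    }
  }
  surrogate_threshold_tfr(tfrs_a, tfrs_b, n_surrogates, percentile, seed)
}

#' @rdname surrogate_threshold
#' @param tfrs_a,tfrs_b Per-subject `nv_tfr` lists for the two channels
#'   (same subject order).
#' @export
surrogate_threshold_tfr <- function(tfrs_a, tfrs_b, n_surrogates = 176,
                                    percentile = 95, seed = 1L) {
  ns <- length(tfrs_a)
  stopifnot(length(tfrs_b) == ns)
  if (ns < 2) {
    stop_nvcoh("Need at least two subjects for inter-subject surrogates.",
               "nvcoh_validation_error")
  }
  if (n_surrogates < 19 && percentile >= 95) {
    stop_nvcoh("A 95th percentile needs at least 19 surrogates.",
               "nvcoh_validation_error")
  }
  pairs <- expand.grid(i = seq_len(ns), j = seq_len(ns))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  if (nrow(pairs) < n_surrogates) {
    stop_nvcoh(sprintf(
      "Only %d ordered cross-subject pairs available; %d surrogates requested.",
      nrow(pairs), n_surrogates), "nvcoh_validation_error")
  }
  take <- with_seed_nv(seed, sample.int(nrow(pairs), n_surrogates))
  pairs <- pairs[take, , drop = FALSE]
  pfa <- lapply(tfrs_a, function(x) {
    if (inherits(x, "nv_tfr")) phasor_field(x) else x
  })
  pfb <- if (identical(tfrs_a, tfrs_b)) pfa else {
    lapply(tfrs_b, function(x) {
      if (inherits(x, "nv_tfr")) phasor_field(x) else x
    })
  }
  ens <- t(vapply(seq_len(n_surrogates), function(s) {
    phasor_coherence(pfa[[pairs$i[s]]], pfb[[pairs$j[s]]])
  }, numeric(length(pfa[[1]]$frequency))))
  k <- ceiling(percentile / 100 * n_surrogates)
  thr <- apply(ens, 2, function(v) sort(v)[k])
  out <- tibble(frequency = pfa[[1]]$frequency, threshold = thr)
  structure(out, class = c("nv_surrogate", class(out)),
            ensemble = ens, pairs = tibble::as_tibble(pairs),
            n_surrogates = n_surrogates, percentile = percentile,
            seed = seed)
}

#' Effective coherence
#'
#' Subtracts the surrogate significance threshold from the raw
#' coherence at each frequency. Values above zero indicate coherence
#' beyond what unlinked records of this length produce. The difference
#' is kept signed (not clipped at zero), so averaging effective
#' coherence over subjects remains unbiased.
#'
#' @param spec A `nv_coherence` from [wavelet_phase_coherence()].
#' @param threshold A `nv_surrogate` table (or data frame with
#'   `frequency`, `threshold`) on the same grid.
#' @return The coherence tibble with columns `threshold` and
#'   `effective = raw - threshold` added.
#' @export
effective_coherence <- function(spec, threshold) {
  stopifnot(is.data.frame(spec), is.data.frame(threshold))
  if (nrow(spec) != nrow(threshold) ||
      !isTRUE(all.equal(spec$frequency, threshold$frequency))) {
    stop_nvcoh("Coherence and threshold are on different grids.",
               "nvcoh_usage_error")
  }
  spec$threshold <- threshold$threshold
  spec$effective <- spec$raw - spec$threshold
  spec
}

#' Band-averaged phase difference
#'
#' Circular mean of the per-frequency phase differences over a band.
#' The sign convention follows the coherence call: positive values mean
#' the first signal leads the second.
#'
#' @param spec A `nv_coherence` object.
#' @param lo,hi Band edges in Hz (half-open).
#' @return Phase difference in radians, in `(-pi, pi]`.
#' @export
band_phase_difference <- function(spec, lo, hi) {
  sel <- spec$frequency >= lo & spec$frequency < hi & !is.na(spec$phase_diff)
  if (!any(sel)) {
    stop_nvcoh("No valid grid frequencies inside [lo, hi).",
               "nvcoh_validation_error")
  }
  circular_mean(spec$phase_diff[sel])
}
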