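# Time-frequency representations: continuous wavelet transform on
# logarithmic frequency grids (Morlet / lognormal mother wavelets),
# Gaussian-windowed Fourier transform on linear grids, power summaries.
#
# All transforms are amplitude-calibrated: a unit-amplitude sinusoid at a
# grid frequency yields coefficients of magnitude ~1 at that frequency.

#' Logarithmic frequency grid
#'
#' Geometric progression of `n_freq` frequencies from `fmin` to `fmax`
#' inclusive. The default analysis grid spans 0.007–4 Hz in 273 steps,
#' giving uniform resolution in log-frequency so that slow vascular
#' oscillations are resolved as well as the cardiac rhythm.
#'
#' @param fmin,fmax Frequency range in Hz, `0 < fmin < fmax`.
#' @param n_freq Number of grid frequencies (>= 2).
#' @return A `nv_grid` object: list with `values` (Hz) and `scale`.
#' @examples
#' make_log_grid(0.007, 4, 273)
#' make_log_grid(1, 4, 3)$values  # 1, 2, 4
#' @export
make_log_grid <- function(fmin = 0.007, fmax = 4, n_freq = 273) {
  assert_scalar_num(fmin, "fmin", positive = TRUE)
  assert_scalar_num(fmax, "fmax", positive = TRUE)
  if (fmin >= fmax || n_freq < 2) {
    stop_nvcoh("Need 0 < fmin < fmax and n_freq >= 2.",
               "nvcoh_validation_error")
  }
  structure(list(values = exp(seq(log(fmin), log(fmax), length.out = n_freq)),
                 scale = "log"),
            class = "nv_grid")
}

#' Linear frequency grid
#'
#' @param fmin,fmax Frequency range in Hz.
#' @param step Grid step in Hz.
#' @return A `nv_grid` object with `scale = "linear"`.
#' @export
make_linear_grid <- function(fmin = 4, fmax = 48, step = 0.1) {
  assert_scalar_num(step, "step", positive = TRUE)
  if (fmin >= fmax || fmin <= 0) {
    stop_nvcoh("Need 0 < fmin < fmax.", "nvcoh_validation_error")
  }
  structure(list(values = seq(fmin, fmax, by = step), scale = "linear"),
            class = "nv_grid")
}

#' @export
print.nv_grid <- function(x, ...) {
  cat(sprintf("<nv_grid %s> %d frequencies, %.4g..%.4g Hz\n",
              x$scale, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# Frequency response of the analytic mother wavelet/window centred at
# grid frequency nu, evaluated at linear frequencies f (Hz). Peak value 2
# (factor 2 restores the amplitude of a real tone from its analytic half).
wavelet_response <- function(f, nu, transform, resolution, sigma_f = NULL) {
  h <- numeric(length(f))
  pos <- f > 0
  if (transform == "WT_morlet") {
    om0 <- 2 * pi * resolution
    h[pos] <- 2 * exp(-om0^2 * (f[pos] - nu)^2 / (2 * nu^2))
  } else if (transform == "WT_lognormal") {
    h[pos] <- 2 * exp(-(2 * pi * resolution * log(f[pos] / nu))^2 / 2)
  } else if (transform == "WFT") {
    h[pos] <- 2 * exp(-(f[pos] - nu)^2 / (2 * sigma_f^2))
  }
  h
}

# Half-width (seconds) of the cone of influence at grid frequency nu:
# the e-folding time of the analytic wavelet's amplitude envelope.
coi_halfwidth <- function(nu, transform, resolution, sigma_f = NULL) {
  switch(transform,
         WT_morlet = sqrt(2) * resolution / nu,
         WT_lognormal = sqrt(2) * resolution / nu,
         WFT = rep(sqrt(2) / (2 * pi * sigma_f), length(nu)))
}

new_tfr <- function(coef, grid, fs, coi_samples, transform, resolution,
                    sigma_f = NULL) {
  structure(list(coef = coef, grid = grid, fs = fs,
                 coi_samples = coi_samples, transform = transform,
                 resolution = resolution, sigma_f = sigma_f),
            class = "nv_tfr")
}

#' @export
print.nv_tfr <- function(x, ...) {
  cat(sprintf("<nv_tfr %s> %d samples x %d frequencies @ %g Hz, resolution %g\n",
              x$transform, nrow(x$coef), ncol(x$coef), x$fs, x$resolution))
  invisible(x)
}

#' Cone-of-influence mask of a time-frequency representation
#'
#' Logical matrix (time x frequency), `TRUE` where the coefficient is
#' farther from either record edge than the wavelet's e-folding support
#' at that frequency, i.e. trustworthy for time averaging.
#'
#' @param tfr A `nv_tfr` object.
#' @return Logical matrix with the same shape as `tfr$coef`.
#' @export
coi_mask <- function(tfr) {
  n <- nrow(tfr$coef)
  idx <- seq_len(n)
  vapply(tfr$coi_samples, function(m) idx > m & idx <= n - m,
         logical(n))
}

# Core engine: FFT-based convolution with reflect padding. Returns the
# complex coefficient matrix (time x frequency).
tf_engine <- function(x, fs, freqs, transform, resolution, sigma_f = NULL) {
  n <- length(x)
  halfw <- coi_halfwidth(freqs, transform, resolution, sigma_f)
  npad <- min(n, ceiling(max(halfw) * fs))
  xp <- c(rev(x[seq_len(npad)]), x, rev(x[(n - npad + 1):n]))
  N <- nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, numeric(N - length(xp)))
  X <- fft(xp)
  fbins <- c(seq(0, floor(N / 2)), seq(-ceiling(N / 2) + 1, -1)) * fs / N
  H <- vapply(freqs, function(nu) {
    wavelet_response(fbins, nu, transform, resolution, sigma_f)
  }, numeric(N))
  W <- stats::mvfft(X * H, inverse = TRUE) / N
  W[npad + seq_len(n), , drop = FALSE]
}

#' Continuous wavelet transform
#'
#' Computes the analytic continuous wavelet transform of a real series
#' on a logarithmic frequency grid. Two mother wavelets are available:
#' Morlet (Gaussian in linear frequency; relative bandwidth set by the
#' frequency-resolution parameter) for power and coherence analysis, and
#' lognormal (Gaussian in log-frequency) for ridge extraction of
#' instantaneous rates. Coefficients are amplitude-calibrated: a tone
#' `A*cos(2*pi*nu0*t)` at a grid frequency produces `|W(nu0, t)| ~ A`.
#' Edge effects are reduced by reflection padding and flagged by the
#' cone-of-influence mask ([coi_mask()]).
#'
#' @param x Real, uniformly sampled series (preprocessed).
#' @param fs Sampling rate in Hz.
#' @param grid A log-scale `nv_grid` with maximum below `fs/2`.
#' @param wavelet `"morlet"` or `"lognormal"`.
#' @param resolution Frequency-resolution parameter (dimensionless;
#'   1 for Morlet power/coherence analysis, 2 for lognormal ridge
#'   extraction). Larger values trade time resolution for frequency
#'   resolution.
#' @return A `nv_tfr` object holding the complex coefficient matrix
#'   (time x frequency), the grid, and the per-frequency cone of
#'   influence.
#' @export
wavelet_transform <- function(x, fs, grid = make_log_grid(),
                              wavelet = c("morlet", "lognormal"),
                              resolution = 1) {
  wavelet <- match.arg(wavelet)
  assert_numeric_series(x)
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(resolution, "resolution", positive = TRUE)
  if (max(grid$values) >= fs / 2) {
    stop_nvcoh("Grid frequencies must stay below the Nyquist frequency.",
               "nvcoh_validation_error")
  }
  transform <- if (wavelet == "morlet") "WT_morlet" else "WT_lognormal"
  coef <- tf_engine(x, fs, grid$values, transform, resolution)
  coi <- pmin(ceiling(coi_halfwidth(grid$values, transform, resolution) * fs),
              floor(length(x) / 2))
  new_tfr(coef, grid, fs, coi, transform, resolution)
}

#' Gaussian-windowed Fourier transform
#'
#' Short-time Fourier coefficients with a Gaussian window on a linear
#' frequency grid, used for EEG bands above delta where linear frequency
#' resolution is conventional. Amplitude calibration matches
#' [wavelet_transform()]. The Gaussian window standard deviation is
#' `window_length / 6` so that +-3 sd span the stated window.
#'
#' @param x Real series.
#' @param fs Sampling rate in Hz.
#' @param grid A linear-scale `nv_grid` within `(0, fs/2)`.
#' @param window_length Window length in seconds (default 1).
#' @return A `nv_tfr` object with `transform = "WFT"`.
#' @export
windowed_fourier_transform <- function(x, fs, grid = make_linear_grid(),
                                       window_length = 1) {
  assert_numeric_series(x)
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (!identical(grid$scale, "linear")) {
    stop_nvcoh("The windowed Fourier transform requires a linear grid.",
               "nvcoh_usage_error")
  }
  if (max(grid$values) >= fs / 2 || min(grid$values) <= 0) {
    stop_nvcoh("Grid must lie within (0, fs/2).", "nvcoh_validation_error")
  }
  sigma_t <- window_length / 6
  sigma_f <- 1 / (2 * pi * sigma_t)
  coef <- tf_engine(x, fs, grid$values, "WFT", NA_real_, sigma_f)
  coi <- rep(min(ceiling(sqrt(2) * sigma_t * fs), floor(length(x) / 2)),
             length(grid$values))
  new_tfr(coef, grid, fs, coi, "WFT", NA_real_, sigma_f)
}

#' Time-averaged power spectrum
#'
#' Per-frequency mean of `|W|^2` over cone-of-influence-valid samples;
#' the wavelet analogue of the Fourier power spectrum. For a unit
#' tone at a grid frequency the peak value is ~1 (so band power is in
#' squared signal units at the amplitude scale; see [total_power()] for
#' the integral calibrated to mean-square units).
#'
#' @param tfr A `nv_tfr` object.
#' @return A tibble (`nv_power_spectrum`) with columns `frequency`,
#'   `power`, `n_valid`. Frequencies whose cone of influence excludes
#'   every sample get `NA` power.
#' @export
time_averaged_power <- function(tfr) {
  stopifnot(inherits(tfr, "nv_tfr"))
  n <- nrow(tfr$coef)
  pw <- vapply(seq_along(tfr$grid$values), function(j) {
    m <- tfr$coi_samples[j]
    if (2 * m >= n) return(c(NA_real_, 0))
    v <- (m + 1):(n - m)
    c(mean(Mod(tfr$coef[v, j])^2), length(v))
  }, numeric(2))
  out <- tibble(frequency = tfr$grid$values, power = pw[1, ],
                n_valid = as.integer(pw[2, ]))
  structure(out, class = c("nv_power_spectrum", class(out)),
            fs = tfr$fs, transform = tfr$transform)
}

# Energy-normalization constant of the transform family: the integral of
# the squared (half-amplitude) response to a unit analytic tone over the
# grid's native measure (d ln f for log grids, d f for linear ones).
# Computed by fine quadrature so total_power is calibrated by
# construction: a unit cosine integrates to its mean square 1/2.
tf_energy_constant <- function(tfr) {
  if (tfr$grid$scale == "log") {
    u <- seq(-6, 6, length.out = 4001)  # u = ln(nu / f_tone)
    h <- wavelet_response(exp(-u), 1, tfr$transform, tfr$resolution,
                          tfr$sigma_f) / 2
    sum((h^2)[-1] + (h^2)[-length(h)]) / 2 * diff(u[1:2])
  } else {
    sf <- tfr$sigma_f
    f <- seq(-8 * sf, 8 * sf, length.out = 4001)
    h <- exp(-f^2 / (2 * sf^2))
    sum((h^2)[-1] + (h^2)[-length(h)]) / 2 * diff(f[1:2])
  }
}

#' Total power in a frequency band
#'
#' Double integral of the squared transform with respect to time and
#' frequency: the frequency integral of `|W|^2` over `[lo, hi)` (in the
#' grid's native measure, with trapezoidal weights), time-averaged over
#' cone-of-influence-valid samples, and normalized by the transform
#' family's energy constant so that a unit-amplitude in-band sinusoid
#' yields its mean square, 0.5.
#'
#' @param tfr A `nv_tfr` object.
#' @param lo,hi Band edges in Hz (half-open `[lo, hi)`).
#' @return Scalar total power in squared signal units.
#' @export
total_power <- function(tfr, lo = NULL, hi = NULL) {
  stopifnot(inherits(tfr, "nv_tfr"))
  f <- tfr$grid$values
  lo <- lo %||% min(f)
  hi <- hi %||% (max(f) + 1e-12)
  sel <- which(f >= lo & f < hi)
  if (length(sel) < 2L) {
    stop_nvcoh("Band [lo, hi) must contain at least two grid frequencies.",
               "nvcoh_validation_error")
  }
  n <- nrow(tfr$coef)
  msk <- coi_mask(tfr)[, sel, drop = FALSE]
  p <- Mod(tfr$coef[, sel, drop = FALSE])^2
  pbar <- colSums(p * msk) / pmax(colSums(msk), 1)
  xs <- if (tfr$grid$scale == "log") log(f[sel]) else f[sel]
  wts <- diff(xs)
  integral <- sum((pbar[-1] + pbar[-length(pbar)]) / 2 * wts)
  integral / (2 * tf_energy_constant(tfr))
}
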