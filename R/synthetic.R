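# Synthetic cohort generator: band-structured oscillations with
# controllable phase coupling, respiratory sinus arrhythmia, 1/f +
# white noise, and optional chorea-like artifact bursts. Every draw is
# reproducible from a master seed via deterministic sub-seed splitting,
# and every generated coupling parameter is returned in a ground-truth
# ledger so tests can predict coherence via exp(-sigma_w^2 / 2).

# Exact discretization of an Ornstein-Uhlenbeck process with unit
# stationary variance (scaled by sd) and correlation time tau seconds.
ou_process <- function(n, fs, tau = 30, sd = 1) {
  a <- exp(-1 / (fs * tau))
  innov_sd <- sqrt(1 - a^2)
  z <- numeric(n)
  z[1] <- rnorm(1)
  e <- rnorm(n - 1, sd = innov_sd)
  for (k in 2:n) z[k] <- a * z[k - 1] + e[k - 1]
  z * sd
}

#' Generate a slowly drifting oscillation phase
#'
#' Integrates an instantaneous frequency `f(t) = f0 * (1 + drift_sd *
#' u(t))`, where `u` is an Ornstein-Uhlenbeck process with unit
#' stationary variance and 30 s correlation time — the package's model
#' of the slow physiological frequency wander that real oscillations
#' exhibit. With `drift_sd = 0` the phase is exactly `2*pi*f0*t`.
#'
#' @param f0 Central frequency in Hz.
#' @param drift_sd Relative frequency drift standard deviation.
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param tau_s Drift correlation time in seconds.
#' @return Phase in radians, length `duration * fs`, starting at 0.
#' @export
gen_phase <- function(f0, drift_sd = 0, duration = 1200, fs = 20,
                      seed = 1L, tau_s = 30) {
  assert_scalar_num(f0, "f0", positive = TRUE)
  if (f0 >= fs / 2) {
    stop_nvcoh("`f0` must be below the Nyquist frequency.",
               "nvcoh_validation_error")
  }
  n <- round(duration * fs)
  f <- if (drift_sd > 0) {
    with_seed_nv(seed, f0 * (1 + drift_sd * ou_process(n, fs, tau_s)))
  } else {
    rep(f0, n)
  }
  2 * pi * c(0, cumsum(f[-n])) / fs
}

#' Generate a pair of phase-coupled oscillations
#'
#' `x = A cos(phi)` and `y = A cos(phi + lag + w)`, sharing the common
#' drifting phase `phi` but separated by a programmed lag and a
#' stationary Gaussian phase jitter `w` (Ornstein-Uhlenbeck, 30 s
#' correlation time, standard deviation `sigma_w`). The expected
#' wavelet phase coherence at the coupling frequency is the Gaussian
#' circular moment `exp(-sigma_w^2 / 2)`, which is what makes this the
#' pipeline's calibration workhorse.
#'
#' @param center_freq Coupling frequency in Hz.
#' @param amplitude Oscillation amplitude.
#' @param sigma_w Phase-jitter standard deviation in radians.
#' @param lag Programmed phase lag in radians (positive: `x` leads).
#' @param drift_sd Relative frequency drift of the shared phase.
#' @param duration,fs Length (s) and sampling rate (Hz).
#' @param seed Integer seed.
#' @return A list with numeric series `x`, `y` and a `truth` list
#'   recording all parameters.
#' @export
gen_coupled_pair <- function(center_freq = 0.1, amplitude = 1,
                             sigma_w = 0.5, lag = 0, drift_sd = 0.05,
                             duration = 1200, fs = 20, seed = 1L) {
  phi <- gen_phase(center_freq, drift_sd, duration, fs,
                   seed = derive_seed(seed, "phase"))
  n <- length(phi)
  w <- if (sigma_w > 0) {
    with_seed_nv(derive_seed(seed, "jitter"),
                 ou_process(n, fs, 30, sigma_w))
  } else {
    numeric(n)
  }
  list(
    x = amplitude * cos(phi),
    y = amplitude * cos(phi + lag + w),
    truth = list(center_freq = center_freq, amplitude = amplitude,
                 sigma_w = sigma_w, lag = lag, drift_sd = drift_sd,
                 expected_wpc = exp(-sigma_w^2 / 2))
  )
}

#' Generate an ECG-like pulse train with respiratory sinus arrhythmia
#'
#' Beat times are obtained by integrating an instantaneous heart rate
#' `r(t) = rate0 + rsa_amp * sin(2*pi*resp_freq*t)` — the respiratory
#' modulation of cardiac frequency — and each beat contributes a sharp
#' Gaussian pulse (20 ms standard deviation). The companion respiration
#' series is returned along with the ground-truth rate.
#'
#' @param rate0 Mean heart rate in Hz.
#' @param rsa_amp Respiratory sinus arrhythmia depth in Hz.
#' @param resp_freq Respiration frequency in Hz.
#' @param duration,fs Length (s) and sampling rate (Hz).
#' @param seed Integer seed (phase of the respiration cycle and pulse
#'   amplitude jitter).
#' @param noise_sd White measurement noise, as a fraction of pulse
#'   amplitude.
#' @return A list with `ecg`, `resp` (numeric series) and `truth`
#'   (containing the instantaneous rate series `rate`).
#' @export
gen_ecg <- function(rate0 = 1.2, rsa_amp = 0.1, resp_freq = 0.25,
                    duration = 1200, fs = 100, seed = 1L,
                    noise_sd = 0.01) {
  stopifnot(rsa_amp < rate0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  r <- rate0 + rsa_amp * sin(2 * pi * resp_freq * t)
  beat_phase <- c(0, cumsum(r[-n])) / fs
  beats <- t[1] + (which(diff(floor(beat_phase)) > 0)) / fs
  ecg <- numeric(n)
  half <- round(0.1 * fs)
  amp_jit <- with_seed_nv(derive_seed(seed, "amp"),
                          1 + 0.05 * rnorm(length(beats)))
  for (b in seq_along(beats)) {
    ctr <- round(beats[b] * fs) + 1
    idx <- max(1, ctr - half):min(n, ctr + half)
    ecg[idx] <- ecg[idx] + amp_jit[b] * exp(-((t[idx] - beats[b])^2) /
                                              (2 * 0.02^2))
  }
  ecg <- ecg + with_seed_nv(derive_seed(seed, "noise"),
                            rnorm(n, sd = noise_sd))
  resp <- sin(2 * pi * resp_freq * t)
  list(ecg = ecg, resp = resp,
       truth = list(rate = r, rate0 = rate0, rsa_amp = rsa_amp,
                    resp_freq = resp_freq))
}

# 1/f (pink) noise by spectral synthesis, unit standard deviation.
pink_noise <- function(n) {
  N <- nextn(n, 2)
  f <- c(1, seq_len(N / 2), rev(seq_len(N / 2 - 1)))
  spec <- rnorm(N) + 1i * rnorm(N)
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x / sd(x)
}

#' Generate a band-structured fNIRS-like channel
#'
#' Sum of drifting oscillatory components (one per requested band) plus
#' 1/f and white noise, emulating the spectral structure of brain
#' oxygenation recordings across the six cardiovascular bands.
#'
#' @param components A tibble/data frame with columns `center_freq`,
#'   `amplitude` and optionally `drift_sd` (default 0.05) and `phase`
#'   (list-column of precomputed phase series for coupling across
#'   channels).
#' @param white_sd,pink_sd Noise standard deviations.
#' @param duration,fs Length (s) and sampling rate (Hz).
#' @param seed Integer seed.
#' @return A list with `x` (the series) and `truth` (per-component
#'   parameters).
#' @export
gen_fnirs_channel <- function(components, white_sd = 0.1, pink_sd = 0.1,
                              duration = 1200, fs = 31.25, seed = 1L) {
  n <- round(duration * fs)
  x <- numeric(n)
  if (!is.null(components) && nrow(components) > 0) {
    if (any(components$center_freq >= fs / 2)) {
      stop_nvcoh("Component frequencies must be below Nyquist.",
                 "nvcoh_validation_error")
    }
    for (i in seq_len(nrow(components))) {
      drift <- if ("drift_sd" %in% names(components)) {
        components$drift_sd[i]
      } else 0.05
      phi <- if ("phase" %in% names(components) &&
                 !is.null(components$phase[[i]])) {
        components$phase[[i]]
      } else {
        gen_phase(components$center_freq[i], drift, duration, fs,
                  seed = derive_seed(seed, "comp", i))
      }
      x <- x + components$amplitude[i] * cos(phi)
    }
  }
  if (pink_sd > 0) {
    x <- x + pink_sd * with_seed_nv(derive_seed(seed, "pink"),
                                    pink_noise(n))
  }
  if (white_sd > 0) {
    x <- x + with_seed_nv(derive_seed(seed, "white"),
                          rnorm(n, sd = white_sd))
  }
  list(x = x, truth = components)
}

#' Add chorea-like artifact bursts
#'
#' Sparse high-amplitude transients at Poisson-distributed times with
#' durations of 0.2–1 s, emulating movement artifacts. Bursts disturb
#' amplitude-based measures while leaving phase-based coherence largely
#' intact, which is the robustness property the analysis relies on for
#' choreatic subjects.
#'
#' @param x Real series.
#' @param fs Sampling rate in Hz.
#' @param rate Bursts per minute.
#' @param amplitude Burst amplitude as a multiple of the signal RMS.
#' @param seed Integer seed.
#' @return The series with bursts added.
#' @export
add_artifact_bursts <- function(x, fs, rate = 2, amplitude = 3, seed = 1L) {
  assert_numeric_series(x)
  if (rate < 0) {
    stop_nvcoh("`rate` must be nonnegative.", "nvcoh_validation_error")
  }
  if (rate == 0) return(x)
  n <- length(x)
  rms <- sqrt(mean(x^2))
  with_seed_nv(seed, {
    n_bursts <- rpois(1, rate * n / fs / 60)
    if (n_bursts == 0) return(x)
    centers <- runif(n_bursts, 0, n / fs)
    durs <- runif(n_bursts, 0.2, 1)
    signs <- sample(c(-1, 1), n_bursts, replace = TRUE)
    t <- (seq_len(n) - 1) / fs
    for (b in seq_len(n_bursts)) {
      idx <- which(abs(t - centers[b]) < durs[b])
      if (!length(idx)) next
      env <- exp(-((t[idx] - centers[b])^2) / (2 * (durs[b] / 4)^2))
      x[idx] <- x[idx] + signs[b] * amplitude * rms * env
    }
    x
  })
}

#' Cohort specification for the synthetic generator
#'
#' Describes a two-group cohort of multichannel recordings with a
#' shared-phase coupling structure. Each subject gets `n_fnirs`
#' fNIRS-like and `n_eeg` EEG-like channels; all channels of a subject
#' share a common drifting phase in the coupling band, and each channel
#' adds its own phase jitter whose standard deviation `sigma_w` is drawn
#' per subject from the group's `sigma_w_mean`/`sigma_w_sd`. The group
#' presets mirror the study design: 13 disease-like vs 29 control
#' subjects ("hd_like"), or two identical null groups.
#'
#' @param n_group1,n_group2 Subjects per group.
#' @param group_labels Group labels, default `c("P", "PC")`.
#' @param n_fnirs,n_eeg Channels per modality.
#' @param coupling_freq Coupled-band centre frequency in Hz (default
#'   0.1, inside the myogenic band).
#' @param sigma_w_mean Length-2 vector: mean per-channel phase jitter
#'   (radians) in group 1 and group 2.
#' @param sigma_w_sd Between-subject standard deviation of the jitter.
#' @param lag Programmed fNIRS-to-EEG phase lag in radians.
#' @param amplitude Oscillation amplitude (signal units).
#' @param drift_sd Relative frequency drift of the shared phase.
#' @param white_sd,pink_sd Channel noise levels.
#' @param artifact_rate Chorea-like bursts per minute (0 = none).
#' @param include_cardio Add an ECG-like pulse train (respiratory sinus
#'   arrhythmia, per-subject heart/respiration rates) and a respiration
#'   channel to each recording.
#' @param duration,fs Length (s) and sampling rate (Hz) of every
#'   channel.
#' @param seed Master seed.
#' @return A `nv_cohort_spec` list.
#' @export
cohort_spec <- function(n_group1 = 13, n_group2 = 29,
                        group_labels = c("P", "PC"),
                        n_fnirs = 3, n_eeg = 3,
                        coupling_freq = 0.1,
                        sigma_w_mean = c(0.7, 0.7), sigma_w_sd = 0.15,
                        lag = pi / 4, amplitude = 1, drift_sd = 0.05,
                        white_sd = 0.3, pink_sd = 0.3,
                        artifact_rate = 0, include_cardio = FALSE,
                        duration = 1200, fs = 10, seed = 1L) {
  stopifnot(n_group1 >= 2, n_group2 >= 2, length(sigma_w_mean) == 2)
  structure(as.list(environment()), class = "nv_cohort_spec")
}

#' @rdname cohort_spec
#' @param ... Overrides passed to [cohort_spec()].
#' @export
cohort_spec_hd_like <- function(...) {
  args <- list(...)
  defaults <- list(sigma_w_mean = c(1.0, 0.7), sigma_w_sd = 0.2)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws every subject's recordings according to a [cohort_spec()]:
#' coupled fNIRS-like and EEG-like channels (common subject phase at
#' the coupling frequency, per-channel jitter, programmed lag), an
#' ECG-like pulse train with respiratory sinus arrhythmia, and a
#' respiration channel. Fully reproducible from the master seed; the
#' returned ledger records each channel's jitter so expected coherences
#' `exp(-sigma_w^2/2)` can be computed by tests.
#'
#' @param spec A `nv_cohort_spec`.
#' @return A list with `recordings` (list of `nv_recording`) and
#'   `ledger` (tibble: subject, group, channel, sigma_w, lag,
#'   amplitude, coupling_freq, seed).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "nv_cohort_spec"))
  groups <- rep(spec$group_labels, c(spec$n_group1, spec$n_group2))
  n <- round(spec$duration * spec$fs)
  recordings <- vector("list", length(groups))
  ledger <- list()
  for (s in seq_along(groups)) {
    g <- match(groups[s], spec$group_labels)
    sseed <- derive_seed(spec$seed, "subject", s)
    phi <- gen_phase(spec$coupling_freq, spec$drift_sd, spec$duration,
                     spec$fs, seed = derive_seed(sseed, "common"))
    sw <- with_seed_nv(derive_seed(sseed, "sigma"),
                       max(0, rnorm(1, spec$sigma_w_mean[g],
                                    spec$sigma_w_sd)))
    labels <- c(paste0("N", seq_len(spec$n_fnirs)),
                probe_layout()$eeg[seq_len(spec$n_eeg)])
    ch <- vector("list", length(labels))
    for (k in seq_along(labels)) {
      cseed <- derive_seed(sseed, "chan", k)
      is_eeg <- k > spec$n_fnirs
      w <- if (sw > 0) {
        with_seed_nv(derive_seed(cseed, "jit"),
                     ou_process(n, spec$fs, 30, sw))
      } else numeric(n)
      lag_k <- if (is_eeg) spec$lag else 0
      x <- spec$amplitude * cos(phi + lag_k + w)
      x <- x + spec$pink_sd * with_seed_nv(derive_seed(cseed, "pink"),
                                           pink_noise(n))
      x <- x + with_seed_nv(derive_seed(cseed, "white"),
                            rnorm(n, sd = spec$white_sd))
      if (spec$artifact_rate > 0) {
        x <- add_artifact_bursts(x, spec$fs, spec$artifact_rate,
                                 seed = derive_seed(cseed, "burst"))
      }
      ch[[k]] <- x
      ledger[[length(ledger) + 1L]] <- tibble(
        subject = sprintf("S%02d", s), group = groups[s],
        channel = labels[k], sigma_w = sw,
        lag = lag_k, amplitude = spec$amplitude,
        coupling_freq = spec$coupling_freq, seed = cseed)
    }
    if (isTRUE(spec$include_cardio)) {
      rate0 <- with_seed_nv(derive_seed(sseed, "hr"), rnorm(1, 1.2, 0.08))
      rfreq <- with_seed_nv(derive_seed(sseed, "rr"), rnorm(1, 0.25, 0.02))
      cardio <- gen_ecg(rate0 = rate0, rsa_amp = 0.08, resp_freq = rfreq,
                        duration = spec$duration, fs = spec$fs,
                        seed = derive_seed(sseed, "ecg"))
      ch <- c(ch, list(cardio$ecg, cardio$resp))
      labels <- c(labels, "ECG", "RESP")
      ledger[[length(ledger) + 1L]] <- tibble(
        subject = sprintf("S%02d", s), group = groups[s], channel = "ECG",
        sigma_w = NA_real_, lag = NA_real_, amplitude = rate0,
        coupling_freq = rfreq, seed = sseed)
    }
    names(ch) <- labels
    recordings[[s]] <- nv_recording(ch, fs = spec$fs,
                                    subject_id = sprintf("S%02d", s),
                                    group_label = groups[s])
  }
  list(recordings = recordings, ledger = dplyr::bind_rows(ledger))
}
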