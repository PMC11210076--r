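test_that("generated phases integrate the programmed frequency", {
  fs <- 20
  phi0 <- gen_phase(0.1, 0, 600, fs, seed = 1)
  t <- time_axis(600, fs)
  expect_equal(phi0, 2 * pi * 0.1 * t)
  # drifting phase: mean rate within 1% of f0 on average over records
  rates <- vapply(1:10, function(s) {
    phi1 <- gen_phase(0.1, 0.1, 1200, fs, seed = s)
    (phi1[length(phi1)] - phi1[1]) / (2 * pi * (length(phi1) - 1) / fs)
  }, numeric(1))
  expect_lt(abs(mean(rates) / 0.1 - 1), 0.01)
  phi1 <- gen_phase(0.1, 0.1, 1200, fs, seed = 2)
  expect_identical(phi1, gen_phase(0.1, 0.1, 1200, fs, seed = 2))
  expect_false(identical(phi1, gen_phase(0.1, 0.1, 1200, fs, seed = 3)))
  expect_error(gen_phase(15, 0, 10, fs), class = "nvcoh_validation_error")
})

test_that("coupled pairs are phase-locked at sigma_w = 0 and lag-accurate", {
  p <- gen_coupled_pair(0.1, sigma_w = 0, lag = 0, duration = 900, fs = 10,
                        seed = 5)
  cc <- wavelet_phase_coherence(
    wavelet_transform(p$x, 10, grid_small()),
    wavelet_transform(p$y, 10, grid_small()))
  j <- which.min(abs(cc$frequency - 0.1))
  expect_gt(cc$raw[j], 0.99)
  expect_equal(p$truth$expected_wpc, 1)
  expect_identical(p$x, gen_coupled_pair(0.1, sigma_w = 0, lag = 0,
                                         duration = 900, fs = 10,
                                         seed = 5)$x)
})

test_that("the ECG generator embeds the programmed rate structure", {
  e <- gen_ecg(rate0 = 1.2, rsa_amp = 0.1, resp_freq = 0.25,
               duration = 600, fs = 100, seed = 9)
  expect_length(e$ecg, 60000)
  expect_equal(mean(e$truth$rate), 1.2, tolerance = 1e-6)
  expect_equal(range(e$truth$rate), c(1.1, 1.3), tolerance = 1e-4)
  # beat count over the record matches the integrated rate
  thr <- 0.5 * max(e$ecg)
  beats <- sum(diff(e$ecg > thr) == 1)
  expect_lt(abs(beats - 1.2 * 600), 4)
  expect_identical(e$ecg, gen_ecg(1.2, 0.1, 0.25, 600, 100, seed = 9)$ecg)
})

test_that("fNIRS-like channels carry calibrated band components", {
  comp <- tibble::tibble(center_freq = 0.1, amplitude = 2)
  ch <- gen_fnirs_channel(comp, white_sd = 0, pink_sd = 0, duration = 1200,
                          fs = 20, seed = 3)
  tfr <- wavelet_transform(ch$x, 20, make_log_grid(0.007, 4, 273))
  expect_lt(abs(total_power(tfr, 0.052, 0.145) / 2 - 1), 0.1)
  # all six cardiovascular band centres produce local power maxima
  centers <- exp((log(cardiovascular_bands()$lo) +
                    log(cardiovascular_bands()$hi)) / 2)
  comp6 <- tibble::tibble(center_freq = centers, amplitude = 1,
                          drift_sd = 0.02)
  ch6 <- gen_fnirs_channel(comp6, white_sd = 0.05, pink_sd = 0,
                           duration = 2400, fs = 20, seed = 4)
  ps <- time_averaged_power(wavelet_transform(ch6$x, 20,
                                              make_log_grid(0.007, 4, 273)))
  for (f0 in centers) {
    j <- which.min(abs(ps$frequency - f0))
    near <- abs(log(ps$frequency / f0)) < 0.25
    far <- abs(log(ps$frequency / f0)) > 0.3 &
      abs(log(ps$frequency / f0)) < 0.45
    expect_gt(max(ps$power[near], na.rm = TRUE),
              2 * min(ps$power[far], na.rm = TRUE))
  }
  expect_error(gen_fnirs_channel(tibble::tibble(center_freq = 15,
                                                amplitude = 1),
                                 duration = 10, fs = 20),
               class = "nvcoh_validation_error")
})

test_that("artifact bursts disturb power but spare phase coherence", {
  p <- gen_coupled_pair(0.1, sigma_w = 0.5, duration = 1200, fs = 10,
                        seed = 6)
  expect_identical(add_artifact_bursts(p$x, 10, rate = 0), p$x)
  xa <- add_artifact_bursts(p$x, 10, rate = 4, amplitude = 4, seed = 7)
  expect_gt(sum(xa^2), 1.1 * sum(p$x^2))  # amplitude metrics disturbed
  g <- grid_small()
  cc0 <- wavelet_phase_coherence(wavelet_transform(p$x, 10, g),
                                 wavelet_transform(p$y, 10, g))
  cc1 <- wavelet_phase_coherence(wavelet_transform(xa, 10, g),
                                 wavelet_transform(p$y, 10, g))
  j <- which.min(abs(g$values - 0.1))
  expect_lt(abs(cc1$raw[j] - cc0$raw[j]), 0.1)  # phase metrics robust
})

test_that("cohorts are reproducible with a complete ground-truth ledger", {
  spec <- cohort_spec(n_group1 = 2, n_group2 = 3, n_fnirs = 2, n_eeg = 1,
                      duration = 120, fs = 5, seed = 33,
                      include_cardio = TRUE)
  ch <- gen_cohort(spec)
  expect_length(ch$recordings, 5)
  expect_equal(vapply(ch$recordings, function(r) r$group_label,
                      character(1)),
               c("P", "P", "PC", "PC", "PC"))
  expect_equal(nrow(ch$recordings[[1]]$channels), 5)  # 2 fNIRS, 1 EEG, ECG, RESP
  expect_true(all(c("N1", "N2", "Fp1", "ECG", "RESP") %in%
                    ch$recordings[[1]]$channels$label))
  # ledger covers every oscillatory channel with its jitter
  expect_true(all(ch$ledger$sigma_w[ch$ledger$channel %in%
                                      c("N1", "N2", "Fp1")] >= 0))
  # byte-identical reproduction from the master seed
  ch2 <- gen_cohort(spec)
  expect_identical(ch$recordings[[3]]$channels$samples,
                   ch2$recordings[[3]]$channels$samples)
  expect_identical(ch$ledger, ch2$ledger)
})
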