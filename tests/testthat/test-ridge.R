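test_that("the ridge of a pure tone sits at the tone frequency", {
  fs <- 20
  g <- make_log_grid(0.6, 2, 60)
  tfr <- wavelet_transform(unit_tone(1.2, 300, fs), fs, g, "lognormal", 2)
  rg <- extract_ridge(tfr, 0.6, 2)
  m <- attr(rg, "coi_samples")
  sel <- (m + 1):(nrow(rg) - m)
  gstep <- mean(diff(log(g$values)))
  expect_lt(max(abs(log(rg$frequency[sel] / 1.2))), gstep)
  # ridge frequency invariant under amplitude scaling
  tfr2 <- wavelet_transform(5 * unit_tone(1.2, 300, fs), fs, g,
                            "lognormal", 2)
  expect_equal(extract_ridge(tfr2, 0.6, 2)$frequency, rg$frequency)
  expect_error(extract_ridge(tfr, 5, 6), class = "nvcoh_validation_error")
})

test_that("the ridge tracks a linear chirp", {
  fs <- 20
  t <- time_axis(300, fs)
  k <- (1.5 - 0.8) / 300
  x <- cos(2 * pi * (0.8 * t + k * t^2 / 2))
  g <- make_log_grid(0.6, 2, 60)
  rg <- extract_ridge(wavelet_transform(x, fs, g, "lognormal", 2), 0.6, 2)
  m <- attr(rg, "coi_samples")
  sel <- (m + 1):(nrow(rg) - m)
  gstep <- mean(diff(log(g$values)))
  err_steps <- log(rg$frequency[sel] / (0.8 + k * t[sel])) / gstep
  expect_lt(sqrt(mean(err_steps^2)), 2)
})

test_that("an infinite jump penalty yields the best constant-frequency path", {
  fs <- 20
  g <- make_log_grid(0.6, 2, 60)
  x <- unit_tone(1.2, 300, fs) + 0.3 * unit_tone(0.8, 300, fs)
  rg <- extract_ridge(wavelet_transform(x, fs, g, "lognormal", 2), 0.6, 2,
                      jump_penalty = Inf)
  expect_equal(sd(rg$frequency), 0)
  expect_lt(abs(rg$frequency[1] - 1.2), 0.03)
})

test_that("a dominant tone wins over a weaker in-band tone at every sample", {
  fs <- 20
  x <- 3 * unit_tone(1.0, 300, fs) + unit_tone(1.4, 300, fs)
  g <- make_log_grid(0.6, 2, 60)
  rg <- extract_ridge(wavelet_transform(x, fs, g, "lognormal", 2), 0.6, 2)
  m <- attr(rg, "coi_samples")
  sel <- (m + 1):(nrow(rg) - m)
  expect_true(all(abs(log(rg$frequency[sel] / 1.0)) < log(1.4 / 1.2)))
})

test_that("ridge modes reconstruct their time series", {
  fs <- 20
  x <- unit_tone(1.0, 300, fs)
  g <- make_log_grid(0.6, 2, 60)
  rg <- extract_ridge(wavelet_transform(x, fs, g, "lognormal", 2), 0.6, 2)
  rec <- reconstruct_mode(rg)
  m <- attr(rg, "coi_samples")
  sel <- (m + 1):(length(x) - m)
  expect_gt(cor(rec[sel], x[sel]), 0.99)
  expect_lt(sqrt(mean((rec[sel] - x[sel])^2)) / sqrt(mean(x[sel]^2)), 0.05)
  # amplitude-modulated tone: envelope recovered
  env <- 1 + 0.4 * cos(2 * pi * 0.02 * time_axis(300, fs))
  rg2 <- extract_ridge(wavelet_transform(env * x, fs, g, "lognormal", 2),
                       0.6, 2)
  expect_lt(sqrt(mean((rg2$amplitude[sel] - env[sel])^2)) /
              sqrt(mean(env[sel]^2)), 0.1)
  # zero-amplitude ridge reconstructs to zero
  rg0 <- rg
  rg0$amplitude <- rep(0, nrow(rg0))
  expect_equal(reconstruct_mode(rg0), rep(0, nrow(rg0)))
})

test_that("instantaneous rate recovers constant and displaced heart rates", {
  e <- gen_ecg(rate0 = 1.2, rsa_amp = 0, resp_freq = 0.25, duration = 300,
               fs = 100, seed = 5)
  r <- instantaneous_rate(e$ecg, 100, 0.6, 2)
  expect_equal(nrow(r), length(e$ecg))  # no interpolation
  expect_lt(max(abs(r$rate - 1.2)), 0.03)
  expect_true(all(r$rate >= 0.6 & r$rate <= 2))
  # a 2.2 Hz heart sits outside the default band but inside 0.8-3 Hz
  e2 <- gen_ecg(rate0 = 2.2, rsa_amp = 0, resp_freq = 0.3, duration = 300,
                fs = 100, seed = 6)
  r2 <- instantaneous_rate(e2$ecg, 100, 0.8, 3)
  expect_lt(median(abs(r2$rate - 2.2)), 0.05)
  expect_error(instantaneous_rate(e$ecg, 100, 2, 1),
               class = "nvcoh_validation_error")
})

test_that("cardiac removal strips an embedded tone but spares clean noise", {
  fs <- 100
  n <- 300 * fs
  set.seed(3)
  noise <- 0.7 * rnorm(n) + 0.7 * nvcoh:::pink_noise(n)
  rmsn <- sqrt(mean(noise^2))
  tone <- rmsn * sqrt(2) * unit_tone(1.1, 300, fs)
  mix <- noise + tone
  clean <- remove_cardiac(mix, fs, 0.6, 2)
  g <- make_log_grid(0.05, 10, 150)
  band_p <- function(z, lo, hi) total_power(wavelet_transform(z, fs, g), lo, hi)
  expect_gt(1 - band_p(clean, 0.6, 2) / band_p(mix, 0.6, 2), 0.8)
  out_ratio <- (band_p(clean, 0.05, 0.55) + band_p(clean, 2.2, 9)) /
    (band_p(mix, 0.05, 0.55) + band_p(mix, 2.2, 9))
  expect_lt(abs(out_ratio - 1), 0.05)
  # no cardiac peak present: output stays close to the input
  clean2 <- remove_cardiac(noise, fs, 0.6, 2)
  expect_lt(sqrt(mean((clean2 - noise)^2)) / rmsn, 0.1)
  # pure tone: almost fully removed
  res <- remove_cardiac(tone, fs, 0.6, 2)
  m <- round(3 * fs / 0.6)
  sel <- m:(n - m)
  expect_lt(sqrt(mean(res[sel]^2)) / sqrt(mean(tone[sel]^2)), 0.1)
})
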