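make_tfr_pair <- function(x, y, fs = 10, g = grid_small()) {
  list(a = wavelet_transform(x, fs, g), b = wavelet_transform(y, fs, g))
}

test_that("self-coherence is one and coherence is amplitude-invariant", {
  set.seed(8)
  x <- rnorm(6000)
  x <- x - mean(x)
  p <- make_tfr_pair(x, x)
  cc <- wavelet_phase_coherence(p$a, p$b)
  expect_true(all(abs(cc$raw - 1) < 1e-9))
  expect_true(all(abs(cc$phase_diff) < 1e-9))
  # scaling + offset (after detrend) leaves coherence unchanged
  y <- detrend_poly(5 * x + 3, 10, 0)
  p2 <- make_tfr_pair(x, y)
  cc2 <- wavelet_phase_coherence(p2$a, p2$b)
  expect_lt(max(abs(cc2$raw - cc$raw)), 1e-9)
  expect_lt(max(abs(cc2$phase_diff)), 1e-9)
})

test_that("coherence is symmetric, phase difference antisymmetric", {
  set.seed(9)
  x <- rnorm(4000)
  y <- rnorm(4000) + 0.5 * x
  p <- make_tfr_pair(x, y)
  ab <- wavelet_phase_coherence(p$a, p$b)
  ba <- wavelet_phase_coherence(p$b, p$a)
  expect_equal(ab$raw, ba$raw, tolerance = 1e-12)
  expect_equal(ab$phase_diff, -ba$phase_diff, tolerance = 1e-9)
  expect_true(all(ab$raw >= 0 & ab$raw <= 1))
  expect_true(all(ab$phase_diff > -pi & ab$phase_diff <= pi))
  expect_error(wavelet_phase_coherence(
    p$a, wavelet_transform(x, 10, make_log_grid(0.05, 0.4, 10))),
    class = "nvcoh_usage_error")
})

test_that("a pure delay maps to the analytic phase difference", {
  fs <- 10
  tau <- 0.5
  t <- time_axis(1800, fs)
  x <- cos(2 * pi * 0.1 * t)
  y <- cos(2 * pi * 0.1 * (t - tau))
  cc <- wavelet_phase_coherence(wavelet_transform(x, fs, grid_small()),
                                wavelet_transform(y, fs, grid_small()))
  j <- which.min(abs(cc$frequency - 0.1))
  expect_lt(abs(cc$phase_diff[j] - 2 * pi * 0.1 * tau), 0.05)
  # identical inputs: zero phase difference (previous test covers raw = 1)
  expect_equal(band_phase_difference(
    wavelet_phase_coherence(wavelet_transform(x, fs, grid_small()),
                            wavelet_transform(x, fs, grid_small())),
    0.05, 0.2), 0, tolerance = 1e-9)
})

test_that("a programmed generator lag is recovered in the band", {
  p <- gen_coupled_pair(0.1, sigma_w = 0.3, lag = pi / 4, duration = 1200,
                        fs = 10, seed = 21)
  cc <- wavelet_phase_coherence(wavelet_transform(p$x, 10, grid_small()),
                                wavelet_transform(p$y, 10, grid_small()))
  # x = first argument leads y by -lag; phase_diff(x, y) = -pi/4
  expect_lt(abs(band_phase_difference(cc, 0.08, 0.125) + pi / 4), 0.1)
})

test_that("effective coherence subtracts the threshold without clipping", {
  spec <- tibble::tibble(frequency = c(0.1, 0.2, 0.3),
                         raw = c(0.6, 0.2, 0.2),
                         phase_diff = c(0, 0, 0), n_valid = c(10L, 10L, 10L))
  thr <- tibble::tibble(frequency = c(0.1, 0.2, 0.3),
                        threshold = c(0.2, 0.2, 0.5))
  eff <- effective_coherence(spec, thr)
  expect_equal(eff$effective, c(0.4, 0, -0.3))
  expect_equal(eff$raw, spec$raw)
  expect_error(effective_coherence(spec, thr[1:2, ]),
               class = "nvcoh_usage_error")
})

test_that("surrogate thresholds are deterministic, nearest-rank and need 2+ subjects", {
  set.seed(10)
  fs <- 5
  g <- make_log_grid(0.05, 0.5, 20)
  tfrs <- lapply(1:6, function(i) wavelet_transform(rnorm(1500), fs, g))
  thr1 <- surrogate_threshold_tfr(tfrs, tfrs, n_surrogates = 20, seed = 3)
  thr2 <- surrogate_threshold_tfr(tfrs, tfrs, n_surrogates = 20, seed = 3)
  expect_identical(thr1$threshold, thr2$threshold)
  ens <- attr(thr1, "ensemble")
  expect_equal(dim(ens), c(20, 20))
  expect_true(all(ens >= 0 & ens <= 1))
  # nearest-rank 95th percentile of 20 surrogates is the 19th order statistic
  expect_equal(thr1$threshold,
               apply(ens, 2, function(v) sort(v)[19]))
  expect_error(surrogate_threshold_tfr(tfrs[1], tfrs[1]),
               "at least")
  expect_error(surrogate_threshold_tfr(tfrs, tfrs, n_surrogates = 100),
               class = "nvcoh_validation_error")
  expect_error(surrogate_threshold_tfr(tfrs, tfrs, n_surrogates = 10),
               class = "nvcoh_validation_error")
})

test_that("surrogate thresholds work from recordings and pair across subjects", {
  set.seed(11)
  recs <- lapply(1:5, function(i) {
    nv_recording(list(N1 = rnorm(1200), O1 = rnorm(1200)), fs = 5,
                 subject_id = sprintf("S%d", i))
  })
  thr <- surrogate_threshold(recs, "N1", "O1", n_surrogates = 20,
                             seed = 2,
                             tf_params = list(grid = make_log_grid(0.05, 0.5,
                                                                   15)))
  expect_equal(nrow(thr), 15)
  expect_true(all(thr$threshold > 0 & thr$threshold < 1))
  pairs <- attr(thr, "pairs")
  expect_true(all(pairs$i != pairs$j))
  expect_equal(anyDuplicated(paste(pairs$i, pairs$j)), 0)
})

test_that("time-localized coherence flags transient coupling", {
  fs <- 5
  dur <- 1500
  g <- make_log_grid(0.05, 0.3, 15)
  phi <- gen_phase(0.1, 0.03, dur, fs, seed = 4)
  n <- length(phi)
  set.seed(12)
  # independent phase outside the coupled window [500, 1000] s
  phi2 <- gen_phase(0.11, 0.05, dur, fs, seed = 5)
  t <- time_axis(dur, fs)
  inwin <- t >= 500 & t <= 1000
  y <- ifelse(inwin, cos(phi + 0.3), cos(phi2))
  tl <- time_localized_wpc(wavelet_transform(cos(phi), fs, g),
                           wavelet_transform(y, fs, g),
                           window_cycles = 10)
  j <- which.min(abs(tl$frequency - 0.1))
  v <- tl$map[, j]
  inside <- mean(v[inwin & !is.na(v)], na.rm = TRUE)
  outside <- mean(v[!inwin], na.rm = TRUE)
  expect_gt(inside, outside + 0.3)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  # identical inputs give a map of ones where defined
  tfr <- wavelet_transform(cos(phi), fs, g)
  tl1 <- time_localized_wpc(tfr, tfr)
  expect_lt(max(abs(tl1$map - 1), na.rm = TRUE), 1e-9)
  # a window longer than the record flags the frequency as missing
  short <- wavelet_transform(cos(phi)[1:300], fs, g)
  tls <- time_localized_wpc(short, short, window_cycles = 50)
  expect_true(all(is.na(tls$map[, 1])))
})
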