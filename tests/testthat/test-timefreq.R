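test_that("log grids are geometric with exact endpoints", {
  g <- make_log_grid(0.007, 4, 273)
  expect_length(g$values, 273)
  expect_equal(g$values[1], 0.007)
  expect_equal(g$values[273], 4)
  ratios <- g$values[-1] / g$values[-273]
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-12)
  expect_equal(make_log_grid(1, 4, 3)$values, c(1, 2, 4))
  expect_error(make_log_grid(2, 2, 1), class = "nvcoh_validation_error")
  expect_error(make_log_grid(-1, 4, 10), class = "nvcoh_validation_error")
})

test_that("wavelet transforms are amplitude-calibrated on single tones", {
  fs <- 20
  x <- unit_tone(0.1, 1200, fs)
  g <- make_log_grid(0.007, 4, 273)
  for (wv in c("morlet", "lognormal")) {
    tfr <- wavelet_transform(x, fs, g, wavelet = wv,
                             resolution = if (wv == "morlet") 1 else 2)
    j <- which.min(abs(g$values - 0.1))
    msk <- coi_mask(tfr)
    med <- median(Mod(tfr$coef[msk[, j], j]))
    expect_lt(abs(med - 1), 0.02)
    # response maximal at the grid frequency nearest the tone
    ps <- time_averaged_power(tfr)
    expect_equal(which.max(ps$power), j)
  }
  expect_error(wavelet_transform(x, fs, make_log_grid(0.01, 15, 50)),
               class = "nvcoh_validation_error")
})

test_that("a zero series transforms to zero coefficients and zero power", {
  tfr <- wavelet_transform(rep(0, 2000), 10, grid_small())
  expect_equal(max(Mod(tfr$coef)), 0)
  expect_equal(max(time_averaged_power(tfr)$power, na.rm = TRUE), 0)
  expect_equal(total_power(tfr), 0)
})

test_that("well-separated tones give separated ridges and additive power", {
  fs <- 20
  x1 <- 1.0 * unit_tone(0.03, 2400, fs)
  x2 <- 1.0 * unit_tone(0.3, 2400, fs)
  g <- make_log_grid(0.007, 4, 273)
  tfr <- wavelet_transform(x1 + x2, fs, g)
  ps <- time_averaged_power(tfr)
  p_mid <- ps$power[which.min(abs(ps$frequency - 0.1))]
  p_t1 <- ps$power[which.min(abs(ps$frequency - 0.03))]
  p_t2 <- ps$power[which.min(abs(ps$frequency - 0.3))]
  expect_lt(p_mid, 0.05 * min(p_t1, p_t2))
  tp_sum <- total_power(wavelet_transform(x1, fs, g)) +
    total_power(wavelet_transform(x2, fs, g))
  expect_lt(abs(total_power(tfr) / tp_sum - 1), 0.05)
})

test_that("the transform is linear and shift-invariant for stationary tones", {
  fs <- 10
  g <- grid_small()
  set.seed(2)
  a <- rnorm(3000); b <- rnorm(3000)
  lhs <- wavelet_transform(2 * a + 3 * b, fs, g)$coef
  rhs <- 2 * wavelet_transform(a, fs, g)$coef +
    3 * wavelet_transform(b, fs, g)$coef
  expect_lt(max(Mod(lhs - rhs)), 1e-9)
  # time shift of a tone leaves |W| unchanged after COI exclusion
  x <- unit_tone(0.1, 900, fs)
  xs <- unit_tone(0.1, 900, fs, phase = 1.3)
  t1 <- wavelet_transform(x, fs, g); t2 <- wavelet_transform(xs, fs, g)
  j <- which.min(abs(g$values - 0.1))
  v <- coi_mask(t1)[, j]
  expect_lt(abs(median(Mod(t1$coef[v, j])) / median(Mod(t2$coef[v, j])) - 1),
            0.01)
})

test_that("total power of a unit in-band tone is its mean square", {
  fs <- 20
  tfr <- wavelet_transform(unit_tone(0.1, 1200, fs), fs,
                           make_log_grid(0.007, 4, 273))
  expect_lt(abs(total_power(tfr, 0.007, 4) - 0.5), 0.05)
  tfr2 <- wavelet_transform(2 * unit_tone(0.1, 1200, fs), fs,
                            make_log_grid(0.007, 4, 273))
  expect_lt(abs(total_power(tfr2) / total_power(tfr) - 4), 0.04)
  expect_error(total_power(tfr, 5, 6), class = "nvcoh_validation_error")
})

test_that("the windowed Fourier transform matches the tone calibration", {
  fs <- 142
  x <- unit_tone(10, 120, fs)
  g <- make_linear_grid(4, 48, 0.1)
  tfr <- windowed_fourier_transform(x, fs, g, window_length = 1)
  j <- which.min(abs(g$values - 10))
  med <- median(Mod(tfr$coef[coi_mask(tfr)[, j], j]))
  expect_lt(abs(med - 1), 0.02)
  expect_equal(max(Mod(windowed_fourier_transform(rep(0, 2000), fs, g)$coef)),
               0)
  expect_error(windowed_fourier_transform(x, fs, make_log_grid(4, 40, 50)),
               class = "nvcoh_usage_error")
})

test_that("the cone of influence widens towards low frequencies", {
  tfr <- wavelet_transform(rnorm(3000), 10, grid_small())
  valid_frac <- colMeans(coi_mask(tfr))
  expect_true(all(diff(valid_frac) >= 0))
  expect_lt(valid_frac[1], valid_frac[length(valid_frac)])
})
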