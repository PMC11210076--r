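# Shared fixtures, built in code.

time_axis <- function(duration, fs) (0:(round(duration * fs) - 1)) / fs

unit_tone <- function(freq, duration, fs, phase = 0) {
  cos(2 * pi * freq * time_axis(duration, fs) + phase)
}

# Least-squares fit of a known-frequency sinusoid; returns amplitude and
# phase so filter gain/phase-shift can be read off the output.
fit_tone <- function(x, freq, fs) {
  t <- time_axis(length(x) / fs, fs)
  X <- cbind(cos(2 * pi * freq * t), sin(2 * pi * freq * t))
  b <- stats::lm.fit(X, x)$coefficients
  list(amplitude = sqrt(sum(b^2)), phase = atan2(-b[2], b[1]))
}

toy_recording <- function(n_channels = 3, n = 100, fs = 20,
                          labels = paste0("N", seq_len(n_channels))) {
  set.seed(42)
  ch <- stats::setNames(lapply(seq_len(n_channels), function(i) rnorm(n)),
                        labels)
  nv_recording(ch, fs = fs, subject_id = "T01", group_label = "SYNTH")
}

grid_small <- function() make_log_grid(0.02, 0.5, 40)
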