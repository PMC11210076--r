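# nvcoh

Multiscale oscillatory analysis and wavelet phase coherence for
simultaneous neurovascular recordings (fNIRS, EEG, ECG, respiration).

## The problem

Brain oxygenation and neuronal activity are coupled through the
neurovascular unit, and both exhibit oscillations over more than three
decades of frequency — from endothelial activity near 0.007 Hz through
the ~0.1 Hz myogenic rhythm up to the cardiac beat and EEG gamma waves.
Whether, and how tightly, two such signals coordinate is captured not
by their amplitudes but by the stability of their phase relationship.
`nvcoh` implements the full analysis chain used to quantify that
coordination in resting-state multichannel recordings, for researchers
studying neurovascular coupling, autonomic function, or any
physiological system of weakly coupled oscillators.

## The method

For each channel pair the package computes, on a logarithmic frequency
grid ν₁ … ν_K (default 0.007–4 Hz, 273 frequencies):

1. **Continuous wavelet transform** W(ν, t) (Morlet mother wavelet,
   frequency resolution 1; lognormal wavelet, resolution 2, for ridge
   extraction), amplitude-calibrated so a tone `A·cos(2πνt)` yields
   `|W(ν,·)| ≈ A`, with a cone-of-influence mask for edge effects.
2. **Wavelet phase coherence**
   `WPC(ν) = | ⟨ exp{i(φ₁(ν,t) − φ₂(ν,t))} ⟩_t |`,
   the magnitude of the time-averaged unit phasor of the phase
   difference: 1 for a perfectly constant phase difference, small for
   unrelated signals. WPC is independent of amplitude by construction.
3. **Inter-subject surrogates**: coherence between channels of
   *different* subjects (default 176 pairings) provides a per-frequency
   null level; the 95th percentile is the significance threshold and
   `effective coherence = raw − threshold`.
4. **Ridge extraction** of instantaneous heart and respiration rates:
   the dynamic-programming amplitude ridge of the ECG wavelet transform
   in 0.6–2 Hz, refined by phase demodulation, gives the heart rate at
   every sample with no beat detection or interpolation.
5. **Band averages and group statistics**: spectra are averaged over
   the canonical cardiovascular bands (endothelial V1/V, neurogenic,
   myogenic, respiratory, cardiac) or EEG bands (δ–γ), compared across
   groups with the Wilcoxon rank-sum test, confirmed by Monte Carlo
   permutation (~16 000 draws), and guarded against multiple
   comparisons with the exact binomial tail probability
   `P(X ≥ k | n tests, p = 0.05)`.

A synthetic-cohort generator (`gen_cohort()`, `gen_coupled_pair()`,
`gen_ecg()`, …) produces band-structured, phase-coupled,
noise-contaminated recordings with known ground truth — coupled pairs
with phase jitter σ_w have expected coherence `exp(−σ_w²/2)` — so every
stage of the pipeline is testable without clinical data.

## Worked example

```r
library(nvcoh)

# a coupled oscillator pair at 0.1 Hz with phase jitter and a pi/4 lag
pair <- gen_coupled_pair(center_freq = 0.1, sigma_w = 0.5, lag = pi/4,
                         duration = 1200, fs = 20, seed = 1)
grid <- make_log_grid(0.007, 4, 273)
wt_x <- wavelet_transform(pair$x, fs = 20, grid)
wt_y <- wavelet_transform(pair$y, fs = 20, grid)
wpc  <- wavelet_phase_coherence(wt_x, wt_y)
wpc[which.min(abs(wpc$frequency - 0.1)), ]
#> # A tibble: 1 × 4
#>   frequency   raw phase_diff n_valid
#>       <dbl> <dbl>      <dbl>   <int>
#> 1     0.100 0.927     -0.808   23434

band_phase_difference(wpc, 0.052, 0.145)
#> [1] -0.8249084
```

The measured coherence at the coupling frequency (0.927) sits near the
programmed expectation `exp(-0.5²/2) = 0.88` (finite records and the
wavelet's time window bias it slightly upward — see the methods
vignette), and the band phase difference recovers the programmed ~π/4
lag with the sign convention that a negative value means the second
signal leads.

Group-level multiplicity is judged with the exact binomial tail; for
example, 36 significant pairs out of 55 at the 5% level:

```r
100 * binomial_tail(36, 55, 0.05)   # percent
#> [1] 1.583409e-31
```

`run_pipeline()` chains every stage (preprocessing → transforms →
coherence → surrogates → band tables → group comparisons) from a single
`pipeline_config()`, and `autoplot()`/`tidy()`/`glance()` methods cover
the result objects. A thin command-line wrapper with `simulate`,
`analyze`, `wpc`, `rate` and `bands` subcommands is installed under
`inst/scripts/nvcoh`.

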