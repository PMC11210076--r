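---
title: "Multiscale oscillations and wavelet phase coherence: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale oscillations and wavelet phase coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nvcoh` analyses simultaneous fNIRS, EEG, ECG and respiration
recordings as a system of coupled oscillators spread over more than
three frequency decades. This vignette explains the models the package
implements, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
and design decisions a careful user should know about.

## 1. Signal model and preprocessing

Each channel is treated as a uniformly sampled real series containing a
sum of oscillatory modes with slowly drifting frequencies, broadband
noise, and slow non-oscillatory trends. Preprocessing removes what is
outside the analysis scope:

* **Polynomial detrend** (`detrend_poly()`, default order 3): removes
  drifts slower than the lowest analysis frequency (0.007 Hz). A
  least-squares fit over the whole segment is subtracted; the operation
  is idempotent and exactly annihilates polynomials up to its order.
* **Zero-phase bandpass** (`bandpass()`): a second-order Butterworth
  high-pass and low-pass in cascade, each applied forward and backward.
  The filter realization was an open choice; Butterworth biquads
  applied via `signal::filtfilt` were chosen because the coherence
  stage depends on phase fidelity — the forward–backward application
  cancels phase shifts exactly in theory, and the implementation keeps
  the residual in-band phase error below 0.01 rad. Running the
  high-pass and low-pass as separate second-order stages (rather than
  one fourth-order bandpass) keeps the recursion numerically safe at
  the extreme normalized cut-off frequencies involved
  (0.007 Hz at 20 Hz sampling is 7·10⁻⁴ of Nyquist). Edges are
  reflect-padded by three high-pass time constants before filtering.
  Defaults: 0.007–4 Hz for cardiovascular analyses, 4–48 Hz for EEG
  above the delta band.
* **Moving-average downsampling** (`downsample_moving_average()`): a
  centred moving average of width `round(fs_in/fs_out)` (zero phase)
  followed by linear interpolation onto the exact output grid, which
  handles non-integer ratios such as 1000 → 142 Hz. Analysis rates are
  fixed presets (`analysis_rates()`): 31.25 Hz for fNIRS–EEG, 20 Hz
  for slow coherence analyses, 142 Hz for fast EEG, 100 Hz before rate
  extraction.
* **Segment choice**: recordings of ~30 min are cut to a continuous
  20-min segment. Which 20 minutes to use is not derivable from first
  principles; the default is the first 1200 s, configurable in
  `extract_segment()`.

## 2. Time–frequency representations

`wavelet_transform()` computes an analytic continuous wavelet transform
on a geometric frequency grid (default 0.007–4 Hz in 273 steps —
uniform resolution in log-frequency, so slow endothelial rhythms are
resolved as well as the cardiac beat). Two mother wavelets are
provided, both defined directly in the frequency domain:

* **Morlet** (resolution parameter `f₀`, default 1): response
  `H_ν(f) = 2·exp(−ω₀²(f−ν)²/2ν²)` with `ω₀ = 2πf₀` — a Gaussian in
  linear frequency with relative bandwidth `1/ω₀`, used for power and
  coherence.
* **Lognormal** (resolution `r`, default 2 for ridge work):
  `H_ν(f) = 2·exp(−(2πr·ln(f/ν))²/2)` — a Gaussian in log-frequency,
  narrower in frequency and therefore better suited to following a
  single mode's instantaneous frequency.

Coefficients are computed by FFT-based convolution with reflection
padding. The **amplitude calibration** is a contract, not a
convention: a tone `A·cos(2πνt)` at a grid frequency gives
`|W(ν,·)| ≈ A` (within 2%), so time-averaged power is in squared
signal units and `total_power()` — the double integral of `|W|²` over
time and frequency — is normalized by the wavelet family's energy
constant (computed by quadrature at run time) so a unit-amplitude
sinusoid integrates to its mean square, 0.5.

The **cone of influence** is the e-folding time of the wavelet
envelope at each frequency (`√2·f₀/ν` for Morlet): samples closer to a
record edge are excluded from every time average. The source material
for this pipeline never defines its edge rule; the e-folding choice is
conservative enough that a 1200-s record retains usable estimates down
to 0.007 Hz while dropping clearly contaminated samples.

`windowed_fourier_transform()` provides the linear-frequency analogue
(Gaussian window; the window length was unstated in the source design,
so 1 s — σ = window/6 — is the default) for EEG bands above delta,
where linear resolution is conventional.

## 3. Ridge extraction and instantaneous rates

`extract_ridge()` finds the frequency path maximizing
`Σ_t [ln|W(ν(t),t)| − λ·(Δ ln ν)²]` by dynamic programming over the
grid (global optimum; Rcpp inner loop). The continuity weight λ
(default 23 in units where slewing at `s` log-frequency units/s costs
`λs²` log-amplitude units/s) makes a physiological heart-rate slew of
~0.3 octave/s cost about one log-amplitude unit per second; the exact
ridge-following scheme is under-specified in the methods this package
follows, so the penalty constant is a package choice with the limit
behaviours pinned by tests (λ→∞ gives the best constant-frequency
path). Ridge frequency is refined below the grid spacing by parabolic
interpolation of log-amplitude in log-frequency, which is exact for
the Gaussian-profile wavelets used.

`instantaneous_rate()` turns an ECG or respiration series into a
gap-free rate series at the input sampling rate. The raw ridge
position alone cannot do this accurately: a wavelet with resolution
r = 2 at 1.2 Hz has a time window of ~1.7 s, which low-passes any rate
modulation near the respiratory frequency — respiratory sinus
arrhythmia at 0.25 Hz would be attenuated to a few percent of its true
depth. The package therefore refines the ridge by **phase
demodulation**: the signal is multiplied by `exp(−iφ_c(t))` built from
the current rate estimate, low-passed with a filter that is flat to
0.4 of the carrier frequency and zero beyond 0.55 (so modulation
sidebands pass with unit gain while the waveform's harmonics, which
land one carrier frequency away after demodulation, are rejected
completely), and the residual phase derivative is added back; two
passes with 0.3-s smoothing are the default. On synthetic ECG with
RSA depth 0.1 Hz this recovers the instantaneous rate with RMS error
~0.01 Hz and ~96% of the modulation amplitude. Edge samples within the
band's cone of influence (plus the smoothing length) are filled with
the nearest interior value so downstream transforms see no gaps.

`remove_cardiac()` subtracts the reconstructed cardiac ridge mode from
EEG. This is deliberately a *single-mode* subtraction, not a full
nonlinear mode decomposition with surrogate-tested harmonics — the
role it plays in this pipeline is only to clear the cardiac line from
the EEG band. A prominence gate (median ridge amplitude ≥ 3× the
median in-band amplitude) keeps the operation from subtracting noise
when no cardiac component is present: a noise-only band yields a ratio
near 2 (Rayleigh statistics of the running maximum), a cardiac line at
unit SNR a ratio near 10.

## 4. Phase coherence and surrogate testing

`wavelet_phase_coherence()` computes, per frequency,
`raw(ν) = |⟨e^{iΔφ}⟩_t|` with `Δφ = φ₁ − φ₂`, over samples valid in
both cones of influence, plus the circular-mean phase difference
(positive = first signal leads). The estimator is invariant under
amplitude scaling of either input by construction.

Finite records give non-zero coherence even for unrelated signals —
increasingly so at low frequencies, where fewer independent cycles fit
the record. `surrogate_threshold()` calibrates this with
**inter-subject surrogates**: coherence between channel a of one
subject and channel b of a *different* subject, which preserves every
within-channel property while removing any physical link. Defaults:
176 ordered cross-subject pairings drawn uniformly at random without
repetition (the combinatorial scheme behind the number 176 is not
published; random ordered pairs is the package's choice, seeded and
recorded), nearest-rank 95th percentile (deterministic and defined for
small ensembles). `effective_coherence()` subtracts the threshold and
deliberately does **not** clip at zero: clipping would bias group
means upward under the null.

Calibration behaviour, verified by the acceptance suite: for
independent noise pairs, ~5% of frequencies exceed the threshold, and
band-averaged effective coherence is negative in expectation (the 95th
percentile sits above the null mean).

### The coupling law and its measurable bias

For the generator's coupled pairs (below), the circular moment of
Gaussian phase jitter gives an expected coherence `exp(−σ_w²/2)`. The
*measured* WPC at 0.1 Hz on a 1200-s record systematically exceeds
this: the wavelet's ~10-s time window at 0.1 Hz low-passes the jitter
process (an Ornstein–Uhlenbeck process with 30-s correlation time
retains only ~71% of its variance after that smoothing), and the
finite record adds the usual positive bias of a mean-phasor magnitude.
Both effects are reproducible analytically and numerically; no choice
of jitter correlation time removes both at once (slower jitter passes
the wavelet but collapses the number of independent jitter samples).
Measured values at σ_w = 0.5/1.0/1.5 run ≈ +0.03/+0.14/+0.18 above the
closed form. The package reports the measured values as they are; the
acceptance suite asserts the idealized ±0.05 band and is expected to
fail it at σ_w ≥ 1 — the monotone decay of coherence with σ_w, which
is what the group comparisons actually rely on, holds throughout.

`time_localized_wpc()` computes coherence in a sliding window of a
fixed number of cycles per frequency (default 10 — short windows bias
coherence upward, 10 cycles bounds that bias while retaining useful
time resolution for transient coupling).

## 5. Band averaging and group statistics

Band definitions (`cardiovascular_bands()`, `eeg_bands()`) use
half-open `[lo, hi)` intervals so touching edges assign each frequency
to exactly one band; the six cardiovascular bands tile 0.007–2 Hz.
`band_average()` is the unweighted arithmetic mean over grid
frequencies in the band — on the log grid this equals uniform
weighting in ln ν, the grid's native measure (the averaging rule was
an open choice; log-uniform matches how the grid samples frequency).

`wilcoxon_ranksum()` uses exact enumeration of all group assignments
of the pooled midranks when the pooled size is ≤ 12 (exact conditional
on ties) and the normal approximation with tie and continuity
correction otherwise; the same vectorized formula drives
`permutation_confirmation()` (random re-assignments at the original
group sizes; confirmation = observed p below the 5th percentile of
permuted p-values). Effect sizes are Cohen's d with pooled (n−1)
standard deviation. Multiplicity is controlled the way the analysis
design prescribes — not by FDR correction but by the exact binomial
tail probability of the observed count of significant pairs
(`binomial_tail()`, computed via the exact tail in log space);
two-sided tests throughout.

## 6. The synthetic-data generator

The generator emulates the features of resting-state neurovascular
recordings that the pipeline is sensitive to:

* **Drifting oscillations**: phases integrate
  `f(t) = f₀(1 + drift·u(t))` with `u` an Ornstein–Uhlenbeck process
  (unit variance, 30-s correlation time) — slow physiological
  frequency wander.
* **Controllable coupling**: channel pairs share a subject-level phase
  and differ by a programmed lag plus OU phase jitter of standard
  deviation σ_w, giving expected coherence `exp(−σ_w²/2)` (subject to
  the measurement bias in §4).
* **Cardio-respiratory structure**: `gen_ecg()` integrates a rate
  `rate₀ + rsa·sin(2π f_resp t)` into beat times and emits 20-ms
  Gaussian pulses — respiratory sinus arrhythmia by construction.
* **Noise**: 1/f plus white noise at configurable levels; optional
  chorea-like artifact bursts (Poisson-timed 0.2–1 s transients) that
  disturb amplitude measures while leaving phase coherence nearly
  intact.

It does **not** attempt biophysical realism: no haemodynamic forward
model, no P/QRS/T morphology, no volume conduction or shared-reference
effects in EEG, no head geometry. Passing tests therefore demonstrate
that the *analysis chain* is correct and calibrated, not that it would
behave identically on every feature of real recordings.

Cohort presets mirror the study design the package targets: group
sizes 13 vs 29, a coupled ~0.1 Hz (myogenic-band) oscillation across
fNIRS-like and EEG-like channels, and an "HD-like" effect implemented
as raised phase jitter (σ_w 1.0 vs 0.7, between-subject SD 0.2) —
chosen a priori from the coherence relation to give a group difference
of about one pooled standard deviation, matching the effect size the
study design was powered for. Generator channel rates default to the
analysis rates rather than acquisition rates (the generator emulates
band-limited oscillatory content, for which they are sufficient).

## 7. Problem sizes used in the automated checks

The test and acceptance runs use desk-scale problem sizes chosen so
Monte Carlo error is small relative to each tolerance: null
calibration with a 14-subject noise cohort (1200 s at 20 Hz, 273
frequencies, 176 surrogates) and 30–40 test pairs; coupling recovery
averaged over 4 pairs per jitter level; rank-sum calibration over 2500
null draws; permutation calibration over 600 replicates of 1000
permutations (the estimator's SE at 200 replicates would be comparable
to the ±2% band being checked); and an end-to-end cohort of 13 vs 29
subjects with 3 fNIRS-like × 3 EEG-like channels analysed at 2 Hz on a
0.03–0.5 Hz grid — the myogenic band sits wholly inside it, and channel
count is a free scale parameter of the montage, not of the statistics.

## 8. Known limitations

* Phase coherence is symmetric: it detects coordination, not direction
  or causality. The band phase difference indicates which oscillation
  leads, nothing more.
* The surrogate scheme assumes subjects are exchangeable under the
  null; systematic cohort-wide artifacts (e.g. mains interference)
  would inflate the threshold rather than produce false positives.
* The measured-coherence bias of §4 means absolute WPC values should
  not be read as exact circular moments; comparisons across groups
  analysed identically are unaffected.
* EDF output quantizes to 16 bits over each channel's range
  (relative error ~1.5·10⁻⁵); the TSV dialect round-trips at full
  double precision.
* No movement-artifact removal is provided; the phase-based measures
  are intrinsically robust to sparse bursts, amplitude-based power
  measures are not.
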