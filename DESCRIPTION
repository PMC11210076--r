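Package: nvcoh
Title: Multiscale Oscillations and Wavelet Phase Coherence for
    Neurovascular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of simultaneous fNIRS, EEG, ECG and respiration
    recordings as systems of coupled oscillators. Implements continuous
    wavelet transforms on logarithmic frequency grids (Morlet and
    lognormal mother wavelets) and Gaussian-windowed Fourier transforms,
    time-averaged and total wavelet power, ridge extraction of
    instantaneous heart and respiration rates, wavelet phase coherence
    with inter-subject surrogate significance thresholds and effective
    coherence, canonical cardiovascular and EEG frequency bands, and
    group statistics (Wilcoxon rank-sum, Monte Carlo permutation
    confirmation, exact binomial multiple-comparison probabilities).
    Ships a synthetic-cohort generator producing band-structured,
    phase-coupled physiological-like signals with known ground truth so
    the whole pipeline can be exercised and calibrated without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
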