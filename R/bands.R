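#' Canonical cardiovascular frequency bands
#'
#' Six bands spanning 0.007–2 Hz, each attributed to a physiological
#' process regulating blood flow and oxygenation: two endothelial bands
#' (NO-independent and NO-dependent), neurogenic, myogenic, respiratory
#' and cardiac. Intervals are half-open `[lo, hi)` so that each boundary
#' frequency belongs to exactly one band and the six bands tile
#' `[0.007, 2)` with no gaps or overlaps.
#'
#' @return A tibble with columns `band` (roman-numeral code), `name`
#'   (process name), `lo` and `hi` (Hz, half-open interval).
#' @examples
#' cardiovascular_bands()
#' @export
cardiovascular_bands <- function() {
  tibble(
    band = c("V1", "V", "IV", "III", "II", "I"),
    name = c("endothelial_no_independent", "endothelial_no_dependent",
             "neurogenic", "myogenic", "respiratory", "cardiac"),
    lo = c(0.007, 0.0095, 0.021, 0.052, 0.145, 0.6),
    hi = c(0.0095, 0.021, 0.052, 0.145, 0.6, 2)
  )
}

#' Canonical EEG frequency bands
#'
#' Classical brain-oscillation bands delta through gamma. Two conventions
#' for the beta/gamma split are supported: beta up to 22 Hz (default, so
#' gamma covers 22–48 Hz) or beta up to 30 Hz. The upper limit of 48 Hz
#' avoids the 50 Hz mains notch. The slow/ultraslow band (0.025–1.5 Hz)
#' overlaps delta and is available separately via [eeg_slow_band()].
#'
#' @param beta_hi Upper edge of the beta band in Hz; one of 22 or 30.
#' @return A tibble with columns `band`, `name`, `lo`, `hi` (Hz).
#' @examples
#' eeg_bands()
#' eeg_bands(beta_hi = 30)
#' @export
eeg_bands <- function(beta_hi = 22) {
  if (!beta_hi %in% c(22, 30)) {
    stop_nvcoh("`beta_hi` must be 22 or 30 Hz.", "nvcoh_validation_error")
  }
  tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.5, 4, 7.5, 14, beta_hi),
    hi = c(4, 7.5, 14, beta_hi, 48)
  )
}

#' @rdname eeg_bands
#' @export
eeg_slow_band <- function() {
  tibble(band = "slow", name = "slow_ultraslow", lo = 0.025, hi = 1.5)
}

#' Look up one frequency band by name
#'
#' @param name Band code or process name, e.g. `"myogenic"`, `"III"`,
#'   `"alpha"`.
#' @param beta_hi Passed to [eeg_bands()].
#' @return A one-row band tibble.
#' @export
band_lookup <- function(name, beta_hi = 22) {
  all <- dplyr::bind_rows(cardiovascular_bands(), eeg_bands(beta_hi),
                          eeg_slow_band())
  hit <- all[all$band == name | all$name == name |
               grepl(name, all$name, fixed = TRUE), , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop_nvcoh(sprintf("Unknown frequency band '%s'.", name),
               "nvcoh_validation_error")
  }
  hit[1L, ]
}

#' Average a spectrum over a frequency band
#'
#' Unweighted arithmetic mean of the spectrum values whose grid
#' frequencies fall in the half-open interval `[lo, hi)`. On the
#' logarithmic grids used throughout the package this corresponds to
#' uniform weighting in log-frequency, the grid's native measure.
#'
#' @param spectrum A data frame with a `frequency` column (Hz), e.g. a
#'   power spectrum from [time_averaged_power()] or a coherence spectrum
#'   from [wavelet_phase_coherence()].
#' @param band A one-row band definition (see [cardiovascular_bands()]),
#'   or a numeric `c(lo, hi)`.
#' @param value Name of the column to average (default `"power"` for
#'   power spectra, `"effective"` then `"raw"` for coherence spectra).
#' @return A scalar.
#' @export
band_average <- function(spectrum, band, value = NULL) {
  if (is.numeric(band) && length(band) == 2L) {
    band <- tibble(lo = band[1], hi = band[2])
  }
  stopifnot(is.data.frame(spectrum), "frequency" %in% names(spectrum))
  if (is.null(value)) {
    value <- intersect(c("power", "effective", "raw"), names(spectrum))[1]
    if (is.na(value)) {
      stop_nvcoh("No value column found; pass `value` explicitly.",
                 "nvcoh_usage_error")
    }
  }
  sel <- spectrum$frequency >= band$lo & spectrum$frequency < band$hi
  if (!any(sel)) {
    stop_nvcoh(sprintf("No grid frequencies inside [%g, %g) Hz.",
                       band$lo, band$hi), "nvcoh_validation_error")
  }
  mean(spectrum[[value]][sel])
}

#' Band-averaged subject-by-pair summary table
#'
#' Collapses per-subject, per-pair spectra to one scalar per cell by
#' band averaging, producing the unit of analysis for the group
#' statistics. Missing subject/pair combinations are kept as explicit
#' `NA` rows rather than imputed.
#'
#' @param results A tibble with columns `subject`, `pair` and a
#'   list-column `spectrum` holding per-pair spectra (coherence or
#'   power), one row per subject x pair.
#' @param band A one-row band definition or numeric `c(lo, hi)`.
#' @param metric `"coherence"` or `"power"`; decides which spectrum
#'   column is averaged (`effective`/`raw` vs `power`).
#' @param value Optional explicit value column name, overriding `metric`.
#' @return A `nv_band_table`: tibble with columns `subject`, `pair`,
#'   `value`, carrying the band and metric as attributes.
#' @export
build_summary_table <- function(results, band,
                                metric = c("coherence", "power"),
                                value = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(results),
            all(c("subject", "pair", "spectrum") %in% names(results)))
  if (is.numeric(band) && length(band) == 2L) {
    edges <- band
    band <- tibble(band = "custom", lo = edges[1], hi = edges[2])
  }
  grids <- unique(vapply(results$spectrum, function(s) {
    if (is.null(s)) NA_real_ else sum(s$frequency)
  }, numeric(1)))
  if (length(stats::na.omit(grids)) > 1L) {
    stop_nvcoh("All spectra must share one frequency grid.",
               "nvcoh_usage_error")
  }
  out <- results
  out$value <- vapply(results$spectrum, function(s) {
    if (is.null(s)) return(NA_real_)
    band_average(s, band, value = value)
  }, numeric(1))
  out <- tidyr::complete(out[c("subject", "pair", "value")],
                         .data$subject, .data$pair)
  structure(out, class = c("nv_band_table", class(out)),
            band = band, metric = metric)
}

#' @importFrom rlang .data
NULL
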