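# Pipeline orchestration: preprocess -> transforms -> (ridges) ->
# coherence -> surrogates -> band summaries -> group statistics, from a
# single config, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the study-design
#' defaults: 0.007–4 Hz log grid with 273 frequencies, 176 inter-subject
#' surrogates at the 95th percentile, 16000 permutations, alpha 0.05,
#' third-order detrend. All overridable.
#'
#' @param analyses Character vector of analyses to run, a subset of
#'   `fnirs_power`, `eeg_power`, `fnirs_fnirs_wpc`, `eeg_eeg_wpc`,
#'   `fnirs_eeg_wpc`, `ihr_fnirs_wpc`, `irr_fnirs_wpc`,
#'   `resp_fnirs_wpc`, `resp_ihr_wpc`.
#' @param grid `nv_grid` for the transforms.
#' @param bands Band table (see [cardiovascular_bands()]) over which to
#'   average.
#' @param beta_hi Beta band convention for EEG bands (22 or 30).
#' @param band_pass `c(lo, hi)` preprocessing passband in Hz.
#' @param detrend_order Polynomial detrend order.
#' @param target_fs Analysis sampling rate in Hz (`NULL` keeps the
#'   recording rate).
#' @param n_surrogates,percentile Surrogate-threshold settings.
#' @param n_permutations Permutation-confirmation draws (0 disables).
#' @param alpha Significance level.
#' @param seed Master seed for surrogate pairing and permutations.
#' @return A `nv_pipeline_config` list.
#' @export
pipeline_config <- function(analyses = "fnirs_eeg_wpc",
                            grid = make_log_grid(0.007, 4, 273),
                            bands = cardiovascular_bands(),
                            beta_hi = 22,
                            band_pass = c(0.007, 4),
                            detrend_order = 3,
                            target_fs = NULL,
                            n_surrogates = 176,
                            percentile = 95,
                            n_permutations = 16000,
                            alpha = 0.05,
                            seed = 1L) {
  known <- c("fnirs_power", "eeg_power", "fnirs_fnirs_wpc", "eeg_eeg_wpc",
             "fnirs_eeg_wpc", "ihr_fnirs_wpc", "irr_fnirs_wpc",
             "resp_fnirs_wpc", "resp_ihr_wpc")
  bad <- setdiff(analyses, known)
  if (length(bad) || !length(analyses)) {
    stop_nvcoh(paste0("Unknown or empty analyses: ",
                      paste(bad, collapse = ", ")), "nvcoh_usage_error")
  }
  structure(as.list(environment())[
    c("analyses", "grid", "bands", "beta_hi", "band_pass", "detrend_order",
      "target_fs", "n_surrogates", "percentile", "n_permutations",
      "alpha", "seed")],
    class = "nv_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments
#'   with `grid` given as `grid: {fmin, fmax, n_freq}`.
#' @return A `nv_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$grid)) {
    args$grid <- make_log_grid(y$grid$fmin, y$grid$fmax, y$grid$n_freq)
  }
  if (!is.null(y$bands) && is.character(y$bands)) {
    args$bands <- if (y$bands == "eeg") eeg_bands(y$beta_hi %||% 22)
    else cardiovascular_bands()
  }
  if (!is.null(args$band_pass)) args$band_pass <- as.numeric(args$band_pass)
  do.call(pipeline_config, args)
}

# Channel sources per analysis side: which labels of a recording feed
# each side of the pair set, and how the raw series is obtained.
channel_set <- function(rec, kind, config) {
  ch <- rec$channels
  pre <- function(x) {
    preprocess_channel(x, rec$fs, config$detrend_order, config$band_pass,
                       config$target_fs)
  }
  switch(kind,
    fnirs = {
      labs <- ch$label[ch$modality == "FNIRS"]
      stats::setNames(lapply(labs, function(l) pre(channel_samples(rec, l))),
                      labs)
    },
    eeg = {
      labs <- ch$label[ch$modality == "EEG"]
      stats::setNames(lapply(labs, function(l) pre(channel_samples(rec, l))),
                      labs)
    },
    resp = list(RESP = pre(channel_samples(rec, "RESP"))),
    ihr = {
      r <- instantaneous_rate(channel_samples(rec, "ECG"), rec$fs,
                              lo = 0.6, hi = min(2, rec$fs / 2 * 0.9))
      list(IHR = pre(r$rate))
    },
    irr = {
      r <- instantaneous_rate(channel_samples(rec, "RESP"), rec$fs,
                              lo = 0.1, hi = 0.5, source = "RESP")
      list(IRR = pre(r$rate))
    })
}

analysis_sides <- function(analysis) {
  switch(analysis,
    fnirs_power = c("fnirs", NA),
    eeg_power = c("eeg", NA),
    fnirs_fnirs_wpc = c("fnirs", "fnirs"),
    eeg_eeg_wpc = c("eeg", "eeg"),
    fnirs_eeg_wpc = c("fnirs", "eeg"),
    ihr_fnirs_wpc = c("ihr", "fnirs"),
    irr_fnirs_wpc = c("irr", "fnirs"),
    resp_fnirs_wpc = c("resp", "fnirs"),
    resp_ihr_wpc = c("resp", "ihr"))
}

run_one_analysis <- function(analysis, cohort, config) {
  sides <- analysis_sides(analysis)
  fs_out <- config$target_fs %||% cohort[[1]]$fs
  # per-subject preprocessed series and transforms for every channel used
  tfr_cache <- lapply(cohort, function(rec) {
    sets <- channel_set(rec, sides[1], config)
    if (!is.na(sides[2]) && sides[2] != sides[1]) {
      sets <- c(sets, channel_set(rec, sides[2], config))
    }
    lapply(sets, function(x) {
      wavelet_transform(x, fs_out, config$grid, wavelet = "morlet",
                        resolution = 1)
    })
  })
  subjects <- vapply(cohort, function(r) r$subject_id, character(1))
  groups <- vapply(cohort, function(r) r$group_label, character(1))
  labels_a <- names(channel_set(cohort[[1]], sides[1], config))

  if (is.na(sides[2])) {                    # power analysis
    results <- purrr::map_dfr(seq_along(cohort), function(s) {
      tibble(subject = subjects[s], group = groups[s], pair = labels_a,
             spectrum = lapply(labels_a, function(l) {
               time_averaged_power(tfr_cache[[s]][[l]])
             }))
    })
    metric <- "power"
  } else {
    labels_b <- names(channel_set(cohort[[1]], sides[2], config))
    pairs <- if (sides[1] == sides[2]) {
      idx <- utils::combn(length(labels_a), 2)
      tibble(a = labels_a[idx[1, ]], b = labels_a[idx[2, ]])
    } else {
      expand.grid(b = labels_b, a = labels_a,
                  stringsAsFactors = FALSE)[, c("a", "b")]
    }
    thresholds <- purrr::map2(pairs$a, pairs$b, function(a, b) {
      n_surr <- min(config$n_surrogates,
                    length(cohort) * (length(cohort) - 1))
      surrogate_threshold_tfr(
        lapply(tfr_cache, `[[`, a), lapply(tfr_cache, `[[`, b),
        n_surrogates = n_surr, percentile = config$percentile,
        seed = derive_seed(config$seed, analysis, a, b))
    })
    results <- purrr::map_dfr(seq_along(cohort), function(s) {
      tibble(subject = subjects[s], group = groups[s],
             pair = paste(pairs$a, pairs$b, sep = "-"),
             spectrum = purrr::map2(seq_len(nrow(pairs)), pairs$a,
                                    function(pi, a) {
               b <- pairs$b[pi]
               raw <- wavelet_phase_coherence(tfr_cache[[s]][[a]],
                                              tfr_cache[[s]][[b]])
               effective_coherence(raw, thresholds[[pi]][
                 c("frequency", "threshold")])
             }))
    })
    metric <- "coherence"
  }

  band_results <- purrr::map(seq_len(nrow(config$bands)), function(bi) {
    band <- config$bands[bi, ]
    if (band$lo >= max(config$grid$values) ||
        band$hi <= min(config$grid$values)) {
      return(NULL)
    }
    tabs <- lapply(unique(groups), function(g) {
      build_summary_table(results[results$group == g, ], band,
                          metric = metric)
    })
    cmp <- if (length(tabs) == 2L) {
      compare_groups(tabs[[1]], tabs[[2]], alpha = config$alpha,
                     n_permutations = config$n_permutations,
                     seed = derive_seed(config$seed, analysis, band$band))
    } else NULL
    list(band = band, tables = stats::setNames(tabs, unique(groups)),
         comparison = cmp)
  })
  names(band_results) <- config$bands$band
  list(analysis = analysis, metric = metric,
       results = results, bands = band_results)
}

#' Run the full analysis pipeline
#'
#' For each configured analysis: preprocess every channel, compute the
#' wavelet transforms, pair-wise phase coherence with inter-subject
#' surrogate thresholds (or time-averaged power), band-average into
#' subject x pair tables per frequency band, and compare the two groups
#' (rank-sum, effect size, optional permutation confirmation, binomial
#' multiplicity summary). Identical cohort, config and seed give
#' identical results.
#'
#' @param cohort A list of `nv_recording` objects covering exactly two
#'   group labels (e.g. from [gen_cohort()]).
#' @param config A `nv_pipeline_config`.
#' @param out_dir Optional output directory; when given, band tables,
#'   comparison tables, multiplicity summaries and a run manifest are
#'   written there as TSV/JSON.
#' @return A `nv_pipeline_result` list: one entry per analysis plus a
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(length(cohort) >= 4, inherits(config, "nv_pipeline_config"))
  groups <- unique(vapply(cohort, function(r) r$group_label, character(1)))
  if (length(groups) != 2L) {
    stop_nvcoh("The cohort must contain exactly two group labels.",
               "nvcoh_usage_error")
  }
  res <- lapply(config$analyses, function(a) {
    tryCatch(run_one_analysis(a, cohort, config),
             error = function(e) {
               stop_nvcoh(sprintf("Stage '%s' failed: %s", a,
                                  conditionMessage(e)), "nvcoh_stage_error")
             })
  })
  names(res) <- config$analyses
  manifest <- list(
    package_version = as.character(utils::packageVersion("nvcoh")),
    seed = config$seed,
    n_subjects = length(cohort),
    groups = groups,
    analyses = config$analyses,
    n_surrogates = config$n_surrogates,
    n_permutations = config$n_permutations,
    grid = list(fmin = min(config$grid$values),
                fmax = max(config$grid$values),
                n_freq = length(config$grid$values))
  )
  out <- structure(c(res, list(manifest = manifest)),
                   class = "nv_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' Write a pipeline result bundle to disk
#'
#' @param result A `nv_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (a in setdiff(names(result), "manifest")) {
    for (b in names(result[[a]]$bands)) {
      br <- result[[a]]$bands[[b]]
      if (is.null(br)) next
      for (g in names(br$tables)) {
        tab <- tidyr::pivot_wider(br$tables[[g]], names_from = "pair",
                                  values_from = "value")
        utils::write.table(tab,
                           file.path(out_dir,
                                     sprintf("%s_%s_%s_table.tsv", a, b, g)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(br$comparison)) {
        utils::write.table(br$comparison$comparisons,
                           file.path(out_dir,
                                     sprintf("%s_%s_comparison.tsv", a, b)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(as.list(br$comparison$summary),
                             file.path(out_dir,
                                       sprintf("%s_%s_summary.json", a, b)),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
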