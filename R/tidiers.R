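# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   scale_x_log10 labs theme_minimal geom_hline scale_fill_viridis_c
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a time-frequency representation
#'
#' @param x A `nv_tfr`.
#' @param downsample Keep every k-th time sample (the full coefficient
#'   grid is large); default keeps ~500 time points.
#' @param ... Unused.
#' @return A tibble with `time`, `frequency`, `amplitude`, `phase`,
#'   `in_coi` (TRUE when inside the unreliable edge region).
#' @method tidy nv_tfr
#' @export
tidy.nv_tfr <- function(x, downsample = NULL, ...) {
  n <- nrow(x$coef)
  ds <- downsample %||% max(1L, floor(n / 500))
  keep <- seq(1L, n, by = ds)
  msk <- coi_mask(x)[keep, , drop = FALSE]
  tibble(
    time = rep((keep - 1) / x$fs, times = ncol(x$coef)),
    frequency = rep(x$grid$values, each = length(keep)),
    amplitude = as.vector(Mod(x$coef[keep, , drop = FALSE])),
    phase = as.vector(Arg(x$coef[keep, , drop = FALSE])),
    in_coi = as.vector(!msk)
  )
}

#' @method glance nv_tfr
#' @export
glance.nv_tfr <- function(x, ...) {
  tibble(transform = x$transform, n_time = nrow(x$coef),
         n_freq = ncol(x$coef), fs = x$fs, resolution = x$resolution,
         fmin = min(x$grid$values), fmax = max(x$grid$values))
}

#' @method autoplot nv_tfr
#' @export
autoplot.nv_tfr <- function(object, ...) {
  d <- tidy.nv_tfr(object)
  ggplot(d[!d$in_coi, ], aes(.data$time, .data$frequency,
                             fill = .data$amplitude^2)) +
    geom_tile() +
    scale_fill_viridis_c(name = "power") +
    ggplot2::scale_y_log10() +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' @method glance nv_coherence
#' @export
glance.nv_coherence <- function(x, ...) {
  tibble(n_freq = nrow(x), fmin = min(x$frequency),
         fmax = max(x$frequency),
         mean_raw = mean(x$raw, na.rm = TRUE),
         mean_effective = if ("effective" %in% names(x)) {
           mean(x$effective, na.rm = TRUE)
         } else NA_real_)
}

#' @method autoplot nv_coherence
#' @export
autoplot.nv_coherence <- function(object, ...) {
  p <- ggplot(object, aes(.data$frequency, .data$raw)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "frequency (Hz)", y = "phase coherence") +
    theme_minimal()
  if ("threshold" %in% names(object)) {
    p <- p + geom_line(aes(y = .data$threshold), colour = "red",
                       linetype = 2)
  }
  p
}

#' @method autoplot nv_power_spectrum
#' @export
autoplot.nv_power_spectrum <- function(object, ...) {
  ggplot(object, aes(.data$frequency, .data$power)) +
    geom_line() +
    (if (attr(object, "transform") == "WFT") list() else scale_x_log10()) +
    labs(x = "frequency (Hz)", y = "time-averaged power") +
    theme_minimal()
}

#' @method tidy nv_group_comparison
#' @export
tidy.nv_group_comparison <- function(x, ...) x$comparisons

#' @method glance nv_group_comparison
#' @export
glance.nv_group_comparison <- function(x, ...) x$summary

#' @method autoplot nv_group_comparison
#' @export
autoplot.nv_group_comparison <- function(object, ...) {
  d <- object$comparisons
  ggplot(d, aes(.data$pair, -log10(.data$p_value),
                colour = .data$direction)) +
    geom_point() +
    geom_hline(yintercept = -log10(0.05), linetype = 2) +
    labs(x = NULL, y = "-log10 p") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method tidy nv_tlwpc
#' @export
tidy.nv_tlwpc <- function(x, ...) {
  tibble(
    time = rep(x$time, times = ncol(x$map)),
    frequency = rep(x$frequency, each = nrow(x$map)),
    coherence = as.vector(x$map)
  )
}

#' @method autoplot nv_tlwpc
#' @export
autoplot.nv_tlwpc <- function(object, ...) {
  d <- tidy.nv_tlwpc(object)
  ggplot(d[!is.na(d$coherence), ],
         aes(.data$time, .data$frequency, fill = .data$coherence)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_log10() +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}
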