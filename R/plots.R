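#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bode plot of a filter specification
#'
#' Magnitude (dB) and phase (degrees, inversion included) of the analytic
#' response over a log-spaced frequency grid.
#'
#' @param object An `al_filter_spec`.
#' @param from,to Frequency range in Hz.
#' @param ... Unused.
#' @return A ggplot object (two stacked panels).
#' @method autoplot al_filter_spec
#' @export
autoplot.al_filter_spec <- function(object, from = 1, to = 100, ...) {
  fr <- frequency_response(object, exp(seq(log(from), log(to), length.out = 400)))
  df <- tidyr::pivot_longer(
    dplyr::mutate(fr, magnitude_db = 20 * log10(.data$magnitude),
                  phase = mfb_phase_deg(object, .data$freq),
                  magnitude = NULL, phase_deg = NULL),
    c("magnitude_db", "phase"), names_to = "panel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = sprintf("MFB band-pass: f0 = %.3g Hz, Q = %.3g",
                                  object$f0, object$Q)) +
    ggplot2::theme_minimal()
}

#' Band-power time course plot
#'
#' @param object An `al_band_trace`.
#' @param ... Unused.
#' @return A ggplot object: channel-mean dB trace over the pre/post axis.
#' @method autoplot al_band_trace
#' @export
autoplot.al_band_trace <- function(object, ...) {
  df <- tibble::tibble(time = object$time,
                       db = colMeans(object$db, na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$db)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s; stimulation period excised at 0)",
                  y = "power (dB re baseline)",
                  title = sprintf("%s band (%g-%g Hz)", object$band$name,
                                  object$band$lo, object$band$hi)) +
    ggplot2::theme_minimal()
}

#' Pipeline results plot
#'
#' Median normalized band-power traces per condition, faceted by band (and
#' array when several were analyzed).
#'
#' @param object An `al_results`.
#' @param stream Stream to plot (default `"total"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot al_results
#' @export
autoplot.al_results <- function(object, stream = "total", ...) {
  df <- object$traces[object$traces$stream == stream, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$db,
                                   colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(band ~ array, labeller = ggplot2::label_both,
                        scales = "free_y") +
    ggplot2::labs(x = "time (s; stimulation excised at 0)",
                  y = "power (dB re baseline)", colour = "condition") +
    ggplot2::theme_minimal()
}

#' Resampling distribution plot
#'
#' @param object An `al_stat`.
#' @param ... Unused.
#' @return A ggplot histogram of the bootstrap/permutation distribution with
#'   the observed value marked.
#' @method autoplot al_stat
#' @export
autoplot.al_stat <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(x = object$dist), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "effect (dB)", y = "draws",
                  title = sprintf("%s: observed %.3g dB, p = %.3g",
                                  object$scheme, object$observed, object$p)) +
    ggplot2::theme_minimal()
}
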