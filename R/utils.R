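#' Analytic signal via the frequency domain
#'
#' Standard FFT construction of the analytic signal (positive frequencies
#' doubled, negative zeroed), used for instantaneous-phase comparisons of
#' filter input and output.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Circular mean of angles in degrees
#'
#' @param deg Angles in degrees.
#' @return Mean direction in `[0, 360)`.
#' @export
circular_mean_deg <- function(deg) {
  z <- mean(exp(1i * deg * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

#' Instantaneous phase difference between two signals
#'
#' Hilbert-transform phase of `y` minus phase of `x`, per sample, in degrees
#' wrapped to `[0, 360)`. Edge samples (10% each side) are dropped to avoid
#' transform edge effects.
#'
#' @param x,y Real numeric vectors of equal length.
#' @return Numeric vector of phase differences (degrees).
#' @export
phase_difference_deg <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  keep <- seq.int(ceiling(n * 0.1), floor(n * 0.9))
  px <- Arg(analytic_signal(x))[keep]
  py <- Arg(analytic_signal(y))[keep]
  ((py - px) * 180 / pi) %% 360
}
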