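#' Design an equal-capacitor MFB band-pass filter
#'
#' Computes component values for the multiple-feedback (MFB) second-order
#' active band-pass topology with both capacitors equal. The topology is
#' naturally inverting, so the midband gain is negative. With equal
#' capacitors `C` the standard relations are
#' \deqn{\omega_0^2 = \frac{R_1+R_3}{R_1 R_2 R_3 C^2}, \qquad
#'       Q = \frac{\omega_0 R_2 C}{2}, \qquad
#'       A_0 = -\frac{R_2}{2 R_1}.}
#' `R3` is realizable only when `2 Q^2 > A0_mag`.
#'
#' @param f0 Center frequency in Hz (> 0).
#' @param Q Quality factor, center frequency over -3 dB bandwidth (> 0).
#' @param A0_mag Magnitude of the midband gain (> 0); the realized gain is
#'   `-A0_mag`.
#' @param C Capacitance in farad of each of the two equal capacitors.
#' @return An object of class `al_filter_spec`: a list with components `R1`,
#'   `R2`, `R3` (ohm), `C` (farad) and derived `f0` (Hz), `Q`, `A0`
#'   (signed midband gain).
#' @examples
#' spec <- design_mfb(12, 1.5)
#' spec$A0           # -1: unity-gain inverting at 12 Hz
#' spec$f0 / spec$Q  # 8 Hz -3 dB bandwidth
#' @export
design_mfb <- function(f0, Q, A0_mag = 1, C = 100e-9) {
  stopifnot(is.numeric(f0), length(f0) == 1, is.numeric(Q), length(Q) == 1)
  if (f0 <= 0) stop("design_mfb: f0 must be strictly positive")
  if (Q <= 0) stop("design_mfb: Q must be strictly positive")
  if (A0_mag <= 0) stop("design_mfb: A0_mag must be strictly positive")
  if (C <= 0) stop("design_mfb: C must be strictly positive")
  if (2 * Q^2 <= A0_mag) {
    stop(sprintf(paste0(
      "design_mfb: unrealizable combination: R3 requires 2*Q^2 > A0_mag ",
      "(got 2*%.3g^2 = %.3g <= %.3g)"), Q, 2 * Q^2, A0_mag))
  }
  w0 <- 2 * pi * f0
  R2 <- 2 * Q / (w0 * C)
  R1 <- Q / (A0_mag * w0 * C)
  R3 <- R1 / (2 * Q^2 / A0_mag - 1)
  mfb_spec(R1 = R1, R2 = R2, R3 = R3, C = C)
}

#' Filter specification from component values
#'
#' Derives (`f0`, `Q`, `A0`) from resistor/capacitor values of the
#' equal-capacitor MFB band-pass stage.
#'
#' @param R1,R2,R3 Resistances in ohm (strictly positive).
#' @param C Capacitance in farad (both capacitors equal; strictly positive).
#' @return An `al_filter_spec` object.
#' @export
mfb_spec <- function(R1, R2, R3, C) {
  vals <- c(R1 = R1, R2 = R2, R3 = R3, C = C)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("mfb_spec: R1, R2, R3 and C must all be finite and strictly positive")
  }
  w0 <- sqrt((R1 + R3) / (R1 * R2 * R3)) / C
  spec <- list(
    R1 = R1, R2 = R2, R3 = R3, C = C,
    f0 = w0 / (2 * pi),
    Q = w0 * R2 * C / 2,
    A0 = -R2 / (2 * R1)
  )
  structure(spec, class = "al_filter_spec")
}

#' @export
print.al_filter_spec <- function(x, ...) {
  cat(sprintf(
    "<MFB band-pass> f0 = %.4g Hz, Q = %.4g, A0 = %.4g (inverting)\n",
    x$f0, x$Q, x$A0))
  cat(sprintf("  R1 = %.4g ohm, R2 = %.4g ohm, R3 = %.4g ohm, C = %.4g F\n",
              x$R1, x$R2, x$R3, x$C))
  invisible(x)
}

#' Flat key-value serialization of a filter spec
#'
#' Component values in SI units; derived quantities are re-computed on read,
#' so the config block is the single source of truth.
#'
#' @param spec An `al_filter_spec`.
#' @return Named numeric vector with elements `R1`, `R2`, `R3`, `C`.
#' @export
filter_spec_config <- function(spec) {
  stopifnot(inherits(spec, "al_filter_spec"))
  c(R1 = spec$R1, R2 = spec$R2, R3 = spec$R3, C = spec$C)
}

#' @rdname filter_spec_config
#' @param config Named numeric vector (or coercible list) with elements
#'   `R1`, `R2`, `R3`, `C`.
#' @export
filter_spec_from_config <- function(config) {
  config <- unlist(config)
  need <- c("R1", "R2", "R3", "C")
  if (!all(need %in% names(config))) {
    stop("filter_spec_from_config: config must name R1, R2, R3, C")
  }
  mfb_spec(config[["R1"]], config[["R2"]], config[["R3"]], config[["C"]])
}

#' Feedback-loop configuration
#'
#' Bundles the non-filter properties of the stimulation chain: the digital
#' recording/conversion delay, the voltage-to-current gain of the constant
#' current stimulator, the hard command limit, and the analog-output
#' (pre-amplifier) gain that maps recorded microvolts onto the filter input.
#'
#' @param digital_delay Delay of the digital components in seconds
#'   (default 0.042, i.e. 175 degrees at 11.6 Hz).
#' @param stim_gain Stimulator transconductance in ampere per volt
#'   (default 2e-3, "2 mA per applied volt").
#' @param command_limit Hard saturation of the command voltage in volt
#'   (default 0.5, giving +/- 1 mA through `stim_gain`).
#' @param sample_rate Sampling rate in Hz for discrete-time use (default 1000).
#' @param preamp_gain Recording-chain gain in volt per microvolt applied
#'   before the filter stage (default 1e-3; in the experiment this gain was
#'   titrated so the loop stayed inside its stability margin).
#' @param polarity +1 or -1; -1 inserts an exact extra 180 degrees into the
#'   loop (command sign inversion), used to flip constructive feedback into
#'   destructive feedback.
#' @return An object of class `al_loop_config`.
#' @export
loop_config <- function(digital_delay = 0.042, stim_gain = 2e-3,
                        command_limit = 0.5, sample_rate = 1000,
                        preamp_gain = 1e-3, polarity = 1) {
  if (digital_delay < 0) stop("loop_config: digital_delay must be >= 0")
  if (stim_gain <= 0) stop("loop_config: stim_gain must be > 0")
  if (command_limit <= 0) stop("loop_config: command_limit must be > 0")
  if (!polarity %in% c(-1, 1)) stop("loop_config: polarity must be +1 or -1")
  structure(list(digital_delay = digital_delay, stim_gain = stim_gain,
                 command_limit = command_limit, sample_rate = sample_rate,
                 preamp_gain = preamp_gain, polarity = polarity),
            class = "al_loop_config")
}

#' Analytic frequency response of the MFB stage
#'
#' Evaluates the band-pass transfer function at physical frequencies. The
#' reported phase includes the topology's inversion, so the phase at exactly
#' `f0` is 180 degrees and the magnitude there is `|A0| = R2 / (2 R1)`.
#'
#' @param spec An `al_filter_spec`.
#' @param freqs Frequencies in Hz (> 0).
#' @return A tibble with columns `freq`, `magnitude` and `phase_deg`
#'   (wrapped to `[0, 360)`).
#' @export
frequency_response <- function(spec, freqs) {
  stopifnot(inherits(spec, "al_filter_spec"))
  if (any(freqs <= 0)) stop("frequency_response: freqs must be > 0")
  w0 <- 2 * pi * spec$f0
  w <- 2 * pi * freqs
  num <- abs(spec$A0) * (w * w0 / spec$Q)
  den <- sqrt((w0^2 - w^2)^2 + (w * w0 / spec$Q)^2)
  tibble::tibble(
    freq = freqs,
    magnitude = num / den,
    phase_deg = mfb_phase_deg(spec, freqs) %% 360
  )
}

# Unwrapped inverting band-pass phase in degrees: continuous and monotone
# decreasing from 270 (f -> 0) through 180 (at f0) to 90 (f -> inf).
mfb_phase_deg <- function(spec, freqs) {
  270 - atan2(freqs * spec$f0 / spec$Q, spec$f0^2 - freqs^2) * 180 / pi
}

#' Total loop phase at a frequency
#'
#' Filter-stage phase (inversion included, unwrapped) plus the linear phase
#' of the digital delay, `360 * f * delay`. Reported unwrapped, so values
#' above 360 degrees are meaningful (one extra cycle).
#'
#' @inheritParams frequency_response
#' @param loop An `al_loop_config`.
#' @param f Frequency in Hz (> 0); vectorized.
#' @return Loop phase in degrees (numeric vector).
#' @examples
#' loop_phase(design_mfb(12, 1.5), loop_config(), 11.6)  # ~361 degrees
#' @export
loop_phase <- function(spec, loop, f) {
  stopifnot(inherits(spec, "al_filter_spec"), inherits(loop, "al_loop_config"))
  if (any(f <= 0)) stop("loop_phase: f must be > 0")
  extra <- if (loop$polarity < 0) 180 else 0
  mfb_phase_deg(spec, f) + 360 * f * loop$digital_delay + extra
}

# Discrete biquad coefficients for the MFB stage: bilinear transform with
# frequency pre-warping at f0 (preserves the center-frequency phase).
# Returns c(b0, b1, b2, a1, a2) with a0 normalized to 1.
mfb_biquad <- function(spec, fs) {
  w0 <- 2 * pi * spec$f0
  if (fs < 10 * spec$f0) {
    stop(sprintf(
      "mfb_biquad: sample rate %g Hz too low for f0 = %g Hz (need fs >= 10*f0)",
      fs, spec$f0))
  }
  K <- w0 / tan(w0 / (2 * fs))
  G <- abs(spec$A0)
  bw <- w0 / spec$Q
  a0 <- K^2 + bw * K + w0^2
  c(-G * bw * K / a0, 0, G * bw * K / a0,       # b0 b1 b2 (sign: inverting)
    (2 * w0^2 - 2 * K^2) / a0,                  # a1
    (K^2 - bw * K + w0^2) / a0)                 # a2
}

#' Apply the filter stage and loop delay to a sampled signal
#'
#' Discrete-time realization of the analog band-pass (bilinear transform,
#' pre-warped at `f0`) applied causally, followed by the digital delay
#' (rounded to samples), polarity, and hard clipping at the command limit.
#' The steady-state response to a pure `f0` sinusoid has amplitude ratio
#' `|A0|` and phase shift `loop_phase(f0)`.
#'
#' @param x Sampled voltage series at the filter input (volt).
#' @param fs Sampling rate in Hz; must be at least `10 * f0`.
#' @inheritParams loop_phase
#' @return Sampled command-voltage series, same length as `x`.
#' @export
apply_filter <- function(x, fs, spec, loop = loop_config(sample_rate = fs)) {
  stopifnot(inherits(spec, "al_filter_spec"), inherits(loop, "al_loop_config"))
  if (!all(is.finite(x))) stop("apply_filter: signal must be finite")
  coefs <- mfb_biquad(spec, fs)
  y <- sos_filter_cpp(matrix(coefs, nrow = 1), as.numeric(x))
  d <- round(loop$digital_delay * fs)
  if (d > 0) y <- c(rep(0, d), y[seq_len(length(y) - d)])
  y <- loop$polarity * y
  pmin(pmax(y, -loop$command_limit), loop$command_limit)
}

# Discrete-time frequency response of the realized biquad at frequencies f.
mfb_biquad_response <- function(spec, fs, f) {
  coefs <- mfb_biquad(spec, fs)
  z <- exp(-2i * pi * f / fs)
  num <- coefs[1] + coefs[2] * z + coefs[3] * z^2
  den <- 1 + coefs[4] * z + coefs[5] * z^2
  num / den
}
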