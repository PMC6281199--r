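#' Time-frequency configuration
#'
#' Wavelet families for the analysis. The low-frequency family increases
#' linearly in both frequency and cycle count (default 5..30 Hz with 5..30
#' cycles, matched index-wise), which fixes the temporal envelope SD at
#' `1/(2*pi)` s for every frequency. The high-gamma family (80-200 Hz) uses
#' `cycles = freq / 2`, i.e. a frequency-independent ~0.08 s envelope.
#'
#' @param freqs Low-frequency grid in Hz, strictly increasing.
#' @param n_cycles Cycle counts matched index-wise to `freqs` (all >= 3).
#' @param hf_freqs High-gamma grid in Hz (set `NULL` to disable).
#' @param hf_cycles Cycle counts for `hf_freqs` (default `hf_freqs / 2`).
#' @param edge_sd Half-support of the wavelet in units of its envelope SD;
#'   samples within this distance of an epoch edge are flagged invalid (NA).
#' @return An `al_tfr_config` object.
#' @export
tfr_config <- function(freqs = 5:30, n_cycles = freqs,
                       hf_freqs = seq(80, 200, by = 5),
                       hf_cycles = hf_freqs / 2, edge_sd = 4) {
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("tfr_config: freqs must be strictly increasing")
  }
  if (length(n_cycles) != length(freqs)) {
    stop("tfr_config: n_cycles must match freqs index-wise")
  }
  if (any(n_cycles < 3) || (length(hf_freqs) && any(hf_cycles < 3))) {
    stop("tfr_config: all cycle counts must be >= 3")
  }
  structure(list(freqs = freqs, n_cycles = n_cycles,
                 hf_freqs = hf_freqs, hf_cycles = hf_cycles,
                 edge_sd = edge_sd),
            class = "al_tfr_config")
}

#' Complex Morlet wavelet
#'
#' Zero-mean complex Morlet wavelet normalized to unit discrete energy
#' (`sum(|w|^2) == 1`); with this convention the expected raw power of white
#' noise is flat across frequencies.
#'
#' @param f Center frequency (Hz).
#' @param n_cycles Number of cycles (sets the envelope SD `n/(2*pi*f)` s).
#' @param fs Sampling rate (Hz).
#' @param edge_sd Half-support in envelope SDs (default 4).
#' @return Complex vector of odd length, centered.
#' @export
morlet_wavelet <- function(f, n_cycles, fs, edge_sd = 4) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(edge_sd * sigma_t * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  # kappa removes the carrier's DC component in continuous time; the final
  # demeaning makes the truncated discrete wavelet exactly zero-mean
  kappa <- exp(-(2 * pi * f * sigma_t)^2 / 2)
  w <- (exp(2i * pi * f * t) - kappa) * env
  w <- w - mean(w)
  w / sqrt(sum(Mod(w)^2))
}

# Morlet power of a time x n_signals matrix via batched FFT convolution.
# Returns power [n_freq, n_time, n_signals] with NA at edge-invalid samples,
# plus the per-frequency half-lengths.
tfr_power_matrix <- function(x, fs, freqs, cycles, edge_sd = 4) {
  nt <- nrow(x); nsig <- ncol(x)
  wl <- lapply(seq_along(freqs), function(i) {
    morlet_wavelet(freqs[i], cycles[i], fs, edge_sd)
  })
  halves <- vapply(wl, function(w) (length(w) - 1L) %/% 2L, integer(1))
  lmax <- max(lengths(wl))
  if (2L * max(halves) >= nt) {
    f_bad <- freqs[which.max(halves)]
    stop(sprintf(paste0(
      "tfr: epoch of %d samples is shorter than twice the wavelet ",
      "half-length at %g Hz"), nt, f_bad))
  }
  N <- stats::nextn(nt + lmax)
  xp <- matrix(0, N, nsig)
  xp[seq_len(nt), ] <- x
  X <- stats::mvfft(xp)
  pow <- array(NA_real_, dim = c(length(freqs), nt, nsig))
  for (i in seq_along(freqs)) {
    p <- tfr_one_freq(X, wl[[i]], halves[i], nt, N)
    pow[i, , ] <- p
  }
  list(power = pow, halves = halves)
}

# power (time x signals) at one frequency from the precomputed signal FFT;
# edge-invalid samples are NA
tfr_one_freq <- function(X, w, h, nt, N) {
  Wf <- stats::fft(c(w, complex(real = rep(0, N - length(w)))))
  conv <- stats::mvfft(X * Wf, inverse = TRUE)[h + seq_len(nt), , drop = FALSE] / N
  p <- Re(conv)^2 + Im(conv)^2
  if (h > 0) {
    p[seq_len(h), ] <- NA_real_
    p[nt - seq_len(h) + 1L, ] <- NA_real_
  }
  p
}

#' Morlet wavelet power of epoched data
#'
#' Convolves every trial and channel with the configured complex Morlet
#' family and returns the squared magnitude. Samples closer to an epoch edge
#' than the wavelet half-support are set to `NA` (edge-invalid), not dropped.
#'
#' @param epochs An `al_epochs` object.
#' @param cfg An `al_tfr_config`.
#' @param family `"lf"` (default, the 5-30 Hz family) or `"hf"` (high gamma).
#' @return An `al_tfr` object: `power` (trials x channels x freqs x time,
#'   uV^2), `freqs`, `time`, `fs`, `stream = "total"`,
#'   `normalization = "raw"`.
#' @export
morlet_power <- function(epochs, cfg = tfr_config(), family = c("lf", "hf")) {
  stopifnot(inherits(epochs, "al_epochs"))
  family <- match.arg(family)
  freqs <- if (family == "lf") cfg$freqs else cfg$hf_freqs
  cycles <- if (family == "lf") cfg$n_cycles else cfg$hf_cycles
  d <- dim(epochs$data)
  pow <- array(NA_real_, dim = c(d[1], d[2], length(freqs), d[3]))
  for (ch in seq_len(d[2])) {
    x <- t(matrix(epochs$data[, ch, ], nrow = d[1]))  # time x trials
    res <- tfr_power_matrix(x, epochs$fs, freqs, cycles, cfg$edge_sd)
    pow[, ch, , ] <- aperm(res$power, c(3, 1, 2))
  }
  structure(list(power = pow, freqs = freqs, time = epochs$time,
                 fs = epochs$fs, condition = epochs$condition,
                 trial_id = epochs$trial_id, channels = epochs$channels,
                 align = epochs$align, stream = "total",
                 normalization = "raw"),
            class = "al_tfr")
}

#' @export
print.al_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr %s/%s> %d trials x %d channels x %d freqs x %d samples\n",
    x$stream, x$normalization, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Across-trial median voltage (evoked potential)
#'
#' Per channel and timepoint, the median voltage across all trials —
#' effectively an evoked potential robust to outlier trials. Callers should
#' pass trials of a single condition.
#'
#' @param epochs An `al_epochs` object.
#' @return An `al_epochs` object with a single pseudo-trial.
#' @export
evoked_median <- function(epochs) {
  stopifnot(inherits(epochs, "al_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 1) stop("evoked_median: need at least one trial")
  ev <- array(NA_real_, dim = c(1, d[2], d[3]))
  for (ch in seq_len(d[2])) {
    m <- matrix(epochs$data[, ch, ], nrow = d[1])
    ev[1, ch, ] <- col_medians_cpp(m)
  }
  out <- epochs
  out$data <- ev
  out$condition <- paste0(unique(epochs$condition), collapse = "+")
  out$trial_id <- 0L
  out$provenance <- c(epochs$provenance, "evoked-median")
  out
}

#' Phase-locked and non-phase-locked power
#'
#' Phase-locked (PL) power is the Morlet power of the across-trial median
#' evoked waveform (a single pseudo-trial). Non-phase-locked (NPL) power is
#' the Morlet power of the individual trials after subtracting that evoked
#' waveform. Trials are grouped by condition; the evoked waveform is computed
#' and subtracted within each condition.
#'
#' @inheritParams morlet_power
#' @return A list with elements `pl` and `npl`, both `al_tfr` objects
#'   (streams `"PL"` and `"NPL"`).
#' @export
pl_npl_power <- function(epochs, cfg = tfr_config(), family = c("lf", "hf")) {
  stopifnot(inherits(epochs, "al_epochs"))
  if (dim(epochs$data)[1] < 2) stop("pl_npl_power: need >= 2 trials")
  family <- match.arg(family)
  conds <- unique(epochs$condition)
  sub <- epochs
  pl_list <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    rows <- which(epochs$condition == conds[i])
    part <- epochs
    part$data <- epochs$data[rows, , , drop = FALSE]
    part$condition <- epochs$condition[rows]
    part$trial_id <- epochs$trial_id[rows]
    ev <- evoked_median(part)
    pl_list[[i]] <- morlet_power(ev, cfg, family)
    pl_list[[i]]$condition <- conds[i]
    sub$data[rows, , ] <- sweep(part$data, c(2, 3), ev$data[1, , ])
  }
  pl <- pl_list[[1]]
  if (length(pl_list) > 1) {
    pl$power <- do.call(abind_trials, lapply(pl_list, `[[`, "power"))
    pl$condition <- vapply(pl_list, `[[`, "", "condition")
    pl$trial_id <- rep(0L, length(pl_list))
  }
  pl$stream <- "PL"
  npl <- morlet_power(sub, cfg, family)
  npl$stream <- "NPL"
  list(pl = pl, npl = npl)
}

# bind 4-d power arrays along the trial dimension
abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3], d[4]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Concatenate onset/offset power epochs into pre/post epochs
#'
#' Joins the pre-onset half (`time < 0`) of onset-aligned power with the
#' post-offset half (`time >= 0`) of offset-aligned power, per trial. The
#' wavelet transform is applied to the full +/-5 s epochs *before* this step,
#' so the stimulation period supports the convolution near the splice and no
#' discontinuity enters any wavelet; edge-invalid (NA) samples at the outer
#' epoch edges are carried through.
#'
#' @param tfr_onset,tfr_offset `al_tfr` objects aligned to onsets / offsets.
#' @return An `al_tfr` with a continuous pre/post time axis (post-offset
#'   `t = 0` is the offset event).
#' @export
concat_prepost_power <- function(tfr_onset, tfr_offset) {
  stopifnot(inherits(tfr_onset, "al_tfr"), inherits(tfr_offset, "al_tfr"))
  if (!setequal(tfr_onset$trial_id, tfr_offset$trial_id)) {
    stop("concat_prepost_power: unmatched trial ids")
  }
  ord <- match(tfr_onset$trial_id, tfr_offset$trial_id)
  pre <- which(tfr_onset$time < 0)
  post <- which(tfr_offset$time >= 0)
  d <- dim(tfr_onset$power)
  out <- tfr_onset
  pow <- array(NA_real_, dim = c(d[1], d[2], d[3], length(pre) + length(post)))
  pow[, , , seq_along(pre)] <- tfr_onset$power[, , , pre, drop = FALSE]
  pow[, , , length(pre) + seq_along(post)] <-
    tfr_offset$power[ord, , , post, drop = FALSE]
  out$power <- pow
  out$time <- c(tfr_onset$time[pre], tfr_offset$time[post])
  out$align <- c("onset", "offset")
  out
}
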