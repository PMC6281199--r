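#' Frequency band definition
#'
#' Bands are closed intervals on the discrete frequency grid, endpoints
#' inclusive — so with the default definitions 15 Hz belongs to both alpha
#' and beta, exactly as the ranges read.
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz (`lo < hi`).
#' @return An `al_band` object.
#' @export
band_def <- function(name, lo, hi) {
  if (!(lo < hi)) stop("band_def: lo must be < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "al_band")
}

#' Default band definitions: alpha 8-15 Hz, beta 15-30 Hz, high gamma
#' 80-200 Hz.
#' @return Named list of `al_band` objects.
#' @export
bands_default <- function() {
  list(alpha = band_def("alpha", 8, 15),
       beta = band_def("beta", 15, 30),
       hgp = band_def("hgp", 80, 200))
}

#' Median-based baseline normalization to decibels
#'
#' Single-trial robust normalization of raw wavelet power, per channel and
#' frequency: (1) each epoch is divided by its own median over the epoch's
#' valid timepoints; (2) at each timepoint the median across epochs is taken;
#' (3) the resulting trace is divided by the grand median of its baseline
#' window; (4) the trace is converted to decibels (`10*log10`). The returned
#' object carries both the collapsed dB trace and the step-1 per-trial tensor
#' retained for resampling, where steps 2-4 are recomputed within each draw.
#'
#' @param tfr A raw `al_tfr` (typically the pre/post concatenated power).
#' @param baseline Baseline window `c(start, end)` s on the epoch time axis.
#' @return An `al_norm` object: `db` (channels x freqs x time), `step1`
#'   (trials x channels x freqs x time), axes, `baseline`, `stream`,
#'   `normalization = "normalized_db"`.
#' @export
normalize_median_db <- function(tfr, baseline = c(-5, -1)) {
  if (!identical(tfr$normalization, "raw")) {
    stop("normalize_median_db: input is already normalized")
  }
  stopifnot(inherits(tfr, "al_tfr"))
  d <- dim(tfr$power)
  step1 <- tfr$power
  for (ch in seq_len(d[2])) {
    for (f in seq_len(d[3])) {
      m <- matrix(tfr$power[, ch, f, ], nrow = d[1])  # trials x time
      valid <- which(!is.na(m[1, ]))
      med <- row_medians_range_cpp(m[, valid, drop = FALSE],
                                   rep(1L, d[1]), rep(length(valid), d[1]))
      if (any(!is.finite(med)) || any(med <= 0)) {
        stop("normalize_median_db: degenerate input (non-positive epoch median)")
      }
      step1[, ch, f, ] <- m / med
    }
  }
  bl <- tfr$time >= baseline[1] & tfr$time <= baseline[2]
  if (!any(bl)) stop("normalize_median_db: baseline window not on time axis")
  db <- array(NA_real_, dim = d[2:4])
  for (ch in seq_len(d[2])) {
    for (f in seq_len(d[3])) {
      m <- matrix(step1[, ch, f, ], nrow = d[1])
      med_t <- col_medians_cpp(m)
      base <- stats::median(med_t[bl], na.rm = TRUE)
      if (!is.finite(base) || base <= 0) {
        stop("normalize_median_db: degenerate baseline median")
      }
      db[ch, f, ] <- 10 * log10(med_t / base)
    }
  }
  structure(list(db = db, step1 = step1, freqs = tfr$freqs, time = tfr$time,
                 fs = tfr$fs, channels = tfr$channels,
                 condition = tfr$condition, trial_id = tfr$trial_id,
                 baseline = baseline, stream = tfr$stream,
                 normalization = "normalized_db"),
            class = "al_norm")
}

#' Band-average a normalized time-frequency object
#'
#' Arithmetic mean of the dB trace over the band's discrete frequencies,
#' endpoints inclusive.
#'
#' @param normalized An `al_norm` object.
#' @param band An `al_band`.
#' @return An `al_band_trace`: `db` (channels x time), `time`, `band`.
#' @export
band_mean <- function(normalized, band) {
  stopifnot(inherits(normalized, "al_norm"), inherits(band, "al_band"))
  sel <- normalized$freqs >= band$lo & normalized$freqs <= band$hi
  if (!any(sel)) stop("band_mean: band outside the computed frequency grid")
  db <- apply(normalized$db[, sel, , drop = FALSE], c(1, 3), mean)
  structure(list(db = db, time = normalized$time, band = band,
                 channels = normalized$channels,
                 condition = normalized$condition, stream = normalized$stream),
            class = "al_band_trace")
}

#' Summarize a band series in a post-offset window
#'
#' Time-mean within the window, per series (trial or channel), plus the
#' overall mean. The window must lie within the post-offset segment of the
#' time axis; the alternate wider window `c(0.5, 1.5)` is supported the same
#' way.
#'
#' @param x An `al_band_trace` (rows = channels) or a numeric matrix with
#'   rows = series (e.g. trials) and columns = timepoints.
#' @param window `c(start, end)` s after stimulation offset.
#' @param time Time axis (s) for matrix input; taken from the object
#'   otherwise.
#' @return A list with `values` (per-series means) and `mean`.
#' @export
window_summary <- function(x, window = c(0.5, 1), time = NULL) {
  if (inherits(x, "al_band_trace")) {
    time <- x$time
    x <- x$db
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(time) || length(time) != ncol(x)) {
    stop("window_summary: need a time axis matching the columns")
  }
  if (window[1] < min(time) || window[2] > max(time)) {
    stop("window_summary: window outside the epoch time axis")
  }
  sel <- time >= window[1] & time <= window[2]
  vals <- rowMeans(x[, sel, drop = FALSE], na.rm = TRUE)
  list(values = vals, mean = mean(vals), window = window)
}

#' Spotlight electrode selection around the controller pair
#'
#' Electrodes on the controller's array whose minimum Manhattan distance on
#' the grid to either controller electrode is at most `radius`, excluding the
#' pair itself.
#'
#' @param map Channel-map tibble (see [channel_map()]).
#' @param radius Manhattan-distance radius (default 2).
#' @return Integer vector of channel numbers.
#' @export
spotlight <- function(map, radius = 2) {
  ctl <- map[map$controller | map$controller_ref, ]
  if (nrow(ctl) != 2) stop("spotlight: map must flag the controller pair")
  cand <- map[map$array == ctl$array[1], ]
  d1 <- abs(cand$row - ctl$row[1]) + abs(cand$col - ctl$col[1])
  d2 <- abs(cand$row - ctl$row[2]) + abs(cand$col - ctl$col[2])
  keep <- pmin(d1, d2) <= radius & !(cand$controller | cand$controller_ref)
  cand$channel[keep]
}

# ---- band tensors: the resampling-ready representation -----------------

# Build the trials x columns matrix backing the per-draw recomputation of
# normalization steps 2-4. `step1` is a trials x freqs x time array of
# epoch-median-normalized power (channel-averaged or single-channel).
# Columns are restricted to the band's frequencies and to the valid baseline
# (optionally strided) and summary-window samples.
band_tensor <- function(step1, freqs, time, band, baseline = c(-5, -1),
                        window = c(0.5, 1), baseline_stride = 1L) {
  stopifnot(length(dim(step1)) == 3)
  fsel <- which(freqs >= band$lo & freqs <= band$hi)
  if (!length(fsel)) stop("band_tensor: band outside the frequency grid")
  n_tr <- dim(step1)[1]
  cols <- list(); colfreq <- integer(0); coltype <- integer(0)
  for (i in seq_along(fsel)) {
    f <- fsel[i]
    valid <- !is.na(step1[1, f, ])
    bsel <- which(valid & time >= baseline[1] & time <= baseline[2])
    bsel <- bsel[seq(1, length(bsel), by = baseline_stride)]
    wsel <- which(valid & time >= window[1] & time <= window[2])
    if (!length(bsel) || !length(wsel)) {
      stop("band_tensor: baseline or window has no valid samples")
    }
    cols[[i]] <- step1[, f, c(bsel, wsel), drop = FALSE]
    colfreq <- c(colfreq, rep(i - 1L, length(bsel) + length(wsel)))
    coltype <- c(coltype, rep(0L, length(bsel)), rep(1L, length(wsel)))
  }
  X <- matrix(unlist(cols), nrow = n_tr)
  structure(list(X = X, colfreq = colfreq, coltype = coltype,
                 nfreq = length(fsel), n_trials = n_tr,
                 band = band, baseline = baseline, window = window),
            class = "al_band_tensor")
}

# Band-window summary (dB) for given trial index sets. `idx` is a matrix
# (draws x selection) or a single vector; defaults to the identity draw.
tensor_summary <- function(tensor, idx = NULL) {
  stopifnot(inherits(tensor, "al_band_tensor"))
  if (is.null(idx)) idx <- seq_len(tensor$n_trials)
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = 1)
  band_summary_draws_cpp(tensor$X, tensor$colfreq, tensor$coltype,
                         tensor$nfreq, idx)
}

# Per-trial summaries against the all-trial baseline, for scalar-path
# statistics: per trial, mean over window columns of
# 10*log10(step1 / baseline_f), with baseline_f the grand baseline median of
# the across-trial median trace.
tensor_trial_values <- function(tensor) {
  med <- col_medians_cpp(tensor$X)
  base <- vapply(seq_len(tensor$nfreq) - 1L, function(f) {
    stats::median(med[tensor$colfreq == f & tensor$coltype == 0L])
  }, numeric(1))
  win <- which(tensor$coltype == 1L)
  sapply(seq_len(tensor$n_trials), function(tr) {
    mean(10 * log10(tensor$X[tr, win] / base[tensor$colfreq[win] + 1L]))
  })
}
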