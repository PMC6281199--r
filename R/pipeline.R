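#' Analysis configuration
#'
#' Bundles every tunable of the offline analysis chain. Defaults follow the
#' standard protocol: -5..+5 s epochs, 11 s (in vivo) / 20 s (in vitro)
#' trial rejection, Morlet family 5-30 Hz with matched cycles, median
#' normalization against a -5..-1 s baseline, band summaries in the
#' 0.5-1.0 s post-offset window, 5000-draw resampling.
#'
#' @param tfr An [tfr_config()].
#' @param bands Named list of [band_def()]s (default [bands_default()]).
#' @param baseline Baseline window (s) on the pre/post axis.
#' @param window Post-offset summary window (s); `c(0.5, 1.5)` is the
#'   supported wider alternative.
#' @param epoch_window Epoching window around events (s).
#' @param reject_limits Named maximum stimulation durations (s) per session
#'   kind.
#' @param stats An [stats_config()].
#' @param streams Power streams to compute: subset of
#'   `c("total", "PL", "NPL")`.
#' @param arrays Arrays to analyze (`NULL` = all arrays in the map).
#' @param stat_array Array whose channel-average drives the condition-level
#'   statistics (default 1, the controlling array).
#' @param array_test Length-2 array ids for the electrode-level array
#'   permutation test, or `NULL` to skip.
#' @param channels Optional explicit channel subset (default: all good,
#'   non-controller channels).
#' @param baseline_stride Stride over baseline samples when recomputing the
#'   grand baseline median inside resampling draws (the observed estimate
#'   uses the same grid; default 1 = every sample).
#' @return An `al_analysis_config` object.
#' @export
analysis_config <- function(tfr = tfr_config(), bands = bands_default(),
                            baseline = c(-5, -1), window = c(0.5, 1),
                            epoch_window = c(-5, 5),
                            reject_limits = c(in_vivo = 11, in_vitro = 20),
                            stats = stats_config(),
                            streams = "total", arrays = NULL,
                            stat_array = 1, array_test = NULL,
                            channels = NULL, baseline_stride = 1L) {
  stopifnot(all(streams %in% c("total", "PL", "NPL")))
  structure(list(tfr = tfr, bands = bands, baseline = baseline,
                 window = window, epoch_window = epoch_window,
                 reject_limits = reject_limits, stats = stats,
                 streams = streams, arrays = arrays, stat_array = stat_array,
                 array_test = array_test, channels = channels,
                 baseline_stride = as.integer(baseline_stride)),
            class = "al_analysis_config")
}

# epochs for a given stream: total -> as-is; PL -> single evoked
# pseudo-trial; NPL -> evoked-subtracted trials
stream_epochs <- function(on, off, stream) {
  if (stream == "total") return(list(on = on, off = off))
  ev_on <- evoked_median(on)
  ev_off <- evoked_median(off)
  if (stream == "PL") return(list(on = ev_on, off = ev_off))
  sub_on <- on; sub_off <- off
  sub_on$data <- sweep(on$data, c(2, 3), ev_on$data[1, , ])
  sub_off$data <- sweep(off$data, c(2, 3), ev_off$data[1, , ])
  list(on = sub_on, off = sub_off)
}

# One wavelet family over one condition's epochs: streams per channel with
# immediate step-1 normalization, accumulating per-array channel averages
# (linear) and per-channel band summaries. Returns time axis, freqs, and
# per-array step-1 tensors [trials, freqs, time].
condition_family_data <- function(on, off, freqs, cycles, edge_sd,
                                  fam_bands, baseline, window,
                                  baseline_stride, per_channel = TRUE) {
  fs <- on$fs
  d <- dim(on$data)
  n_tr <- d[1]; n_ch <- d[2]
  pre_idx <- which(on$time < 0)
  post_idx <- which(off$time >= 0)
  time_cat <- c(on$time[pre_idx], off$time[post_idx])
  n_tc <- length(time_cat)
  arr_of_ch <- on$channels$array
  arrays <- sort(unique(arr_of_ch))
  # accumulators in [time, freq, trial] layout (transposed once at the end)
  acc <- lapply(arrays, function(a) {
    array(0, dim = c(n_tc, length(freqs), n_tr))
  })
  names(acc) <- as.character(arrays)
  n_in_arr <- table(factor(arr_of_ch, levels = arrays))
  chan_rows <- list()
  wl <- lapply(seq_along(freqs), function(i) {
    morlet_wavelet(freqs[i], cycles[i], fs, edge_sd)
  })
  halves <- vapply(wl, function(w) (length(w) - 1L) %/% 2L, integer(1))
  if (2L * max(halves) >= d[3]) {
    stop(sprintf("pipeline: epoch too short for the %g Hz wavelet",
                 freqs[which.max(halves)]))
  }
  N <- stats::nextn(d[3] + max(lengths(wl)))
  pad <- function(m) { out <- matrix(0, N, n_tr); out[seq_len(d[3]), ] <- m; out }
  for (ch in seq_len(n_ch)) {
    X_on <- stats::mvfft(pad(t(matrix(on$data[, ch, ], nrow = n_tr))))
    X_off <- stats::mvfft(pad(t(matrix(off$data[, ch, ], nrow = n_tr))))
    a <- as.character(arr_of_ch[ch])
    st1 <- if (per_channel) {
      array(NA_real_, dim = c(n_tr, length(freqs), n_tc))
    }
    for (f in seq_along(freqs)) {
      p_on <- tfr_one_freq(X_on, wl[[f]], halves[f], d[3], N)
      p_off <- tfr_one_freq(X_off, wl[[f]], halves[f], d[3], N)
      m <- rbind(p_on[pre_idx, , drop = FALSE],
                 p_off[post_idx, , drop = FALSE])
      valid <- which(!is.na(m[, 1]))
      med <- col_medians_cpp(m[valid, , drop = FALSE])
      if (any(!is.finite(med)) || any(med <= 0)) {
        stop("pipeline: degenerate epoch median (channel ",
             on$channels$channel[ch], ", ", freqs[f], " Hz)")
      }
      m <- m * rep(1 / med, each = n_tc)
      acc[[a]][, f, ] <- acc[[a]][, f, ] + m / n_in_arr[[a]]
      if (per_channel) st1[, f, ] <- t(m)
    }
    if (per_channel) {
      for (bn in names(fam_bands)) {
        b <- fam_bands[[bn]]
        tens <- band_tensor(st1, freqs, time_cat, b, baseline, window,
                            baseline_stride)
        chan_rows[[length(chan_rows) + 1L]] <- tibble::tibble(
          channel = on$channels$channel[ch], array = arr_of_ch[ch],
          band = bn, value = tensor_summary(tens))
      }
    }
  }
  acc <- lapply(acc, function(x) aperm(x, c(3, 2, 1)))
  list(step1 = acc, freqs = freqs, time = time_cat,
       per_channel = dplyr::bind_rows(chan_rows))
}

#' Run the full offline analysis pipeline
#'
#' Executes prep (epoching, trial rejection, channel exclusion), the Morlet
#' transform with power-domain pre/post concatenation, median normalization,
#' band/window summaries and the resampling statistics, for each requested
#' power stream. Epochs of the same condition are pooled across sessions.
#'
#' Statistics: per condition x band, a bootstrap of the channel-averaged
#' post-offset band power against zero (on `stat_array`); per condition pair
#' x band, a label permutation test (groups are subsampled to the smaller
#' size when the Brain condition's count differs); optionally, per condition
#' x band, an electrode-level array permutation test between two arrays
#' (total stream only). FDR correction is applied within each band's family
#' of condition pairs (and likewise within the bootstrap and array families).
#'
#' @param sessions An `al_session` or list of them (same channel map).
#' @param config An [analysis_config()].
#' @return An `al_results` object with tibbles `summary` (estimates and CIs
#'   per condition/array/band/stream), `stats` (all tests with `p` and
#'   `p_fdr`), `traces` (median dB time courses for plotting) and a `log`
#'   list (seeds, config hash, trial/channel counts).
#' @export
run_pipeline <- function(sessions, config = analysis_config()) {
  if (inherits(sessions, "al_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  cfg <- config
  # ---- prep ------------------------------------------------------------
  pooled_on <- list(); pooled_off <- list()
  n_rejected <- 0L; n_kept <- 0L
  channels <- cfg$channels
  if (is.null(channels)) {
    # channels flagged bad in any pooled session are excluded everywhere
    per_sess <- lapply(sessions, select_channels, array = cfg$arrays)
    channels <- Reduce(intersect, per_sess)
    if (!length(channels)) {
      stop("run_pipeline: no common analysis channels across sessions")
    }
  }
  for (s in sessions) {
    limit <- cfg$reject_limits[[s$kind]]
    kept <- reject_trials(s$events, max_duration = limit)
    n_rejected <- n_rejected + length(unique(s$events$trial_id)) - length(kept)
    n_kept <- n_kept + length(kept)
    if (length(kept) == 0) {
      stop("run_pipeline: no trials survive rejection in a session")
    }
    pooled_on[[length(pooled_on) + 1L]] <-
      epoch_events(s, "onset", cfg$epoch_window, channels = channels,
                   trials = kept)
    pooled_off[[length(pooled_off) + 1L]] <-
      epoch_events(s, "offset", cfg$epoch_window, channels = channels,
                   trials = kept)
  }
  on_all <- pool_epochs(pooled_on)
  off_all <- pool_epochs(pooled_off)
  # ---- families needed -------------------------------------------------
  fs <- on_all$fs
  fam_of_band <- vapply(cfg$bands, function(b) {
    if (b$lo >= min(cfg$tfr$freqs) && b$hi <= max(cfg$tfr$freqs)) "lf"
    else "hf"
    }, character(1))
  use_hf <- any(fam_of_band == "hf")
  if (use_hf &&
      (!length(cfg$tfr$hf_freqs) || fs < 2 * max(cfg$tfr$hf_freqs))) {
    fam_of_band <- fam_of_band[fam_of_band != "hf"]
    use_hf <- FALSE
  }
  bands_lf <- cfg$bands[names(fam_of_band)[fam_of_band == "lf"]]
  bands_hf <- cfg$bands[names(fam_of_band)[fam_of_band == "hf"]]
  conds <- sort(unique(on_all$condition))
  # ---- per condition / stream / family computation ---------------------
  tensors <- list(); per_channel <- list(); traces <- list()
  summary_rows <- list()
  for (cond in conds) {
    rows <- which(on_all$condition == cond)
    on_c <- subset_epochs(on_all, rows)
    off_c <- subset_epochs(off_all, rows)
    for (stream in cfg$streams) {
      se <- stream_epochs(on_c, off_c, stream)
      want_pc <- !is.null(cfg$array_test) && stream == "total"
      fams <- list()
      fams$lf <- condition_family_data(se$on, se$off, cfg$tfr$freqs,
                                       cfg$tfr$n_cycles, cfg$tfr$edge_sd,
                                       bands_lf, cfg$baseline, cfg$window,
                                       cfg$baseline_stride, want_pc)
      if (use_hf) {
        fams$hf <- condition_family_data(se$on, se$off, cfg$tfr$hf_freqs,
                                         cfg$tfr$hf_cycles, cfg$tfr$edge_sd,
                                         bands_hf, cfg$baseline, cfg$window,
                                         cfg$baseline_stride, want_pc)
      }
      for (bn in names(fam_of_band)) {
        fam <- fams[[fam_of_band[[bn]]]]
        for (a in names(fam$step1)) {
          tens <- band_tensor(fam$step1[[a]], fam$freqs, fam$time,
                              cfg$bands[[bn]], cfg$baseline, cfg$window,
                              cfg$baseline_stride)
          key <- paste(cond, stream, bn, a, sep = ".")
          tensors[[key]] <- tens
          est <- tensor_summary(tens)
          summary_rows[[key]] <- tibble::tibble(
            condition = cond, stream = stream, band = bn,
            array = as.integer(a), estimate = est,
            n_trials = tens$n_trials)
          # median dB time course for plotting / traces table
          med <- t(vapply(seq_along(fam$freqs), function(f) {
            m <- matrix(fam$step1[[a]][, f, ], nrow = dim(fam$step1[[a]])[1])
            col_medians_cpp(m)
          }, numeric(length(fam$time))))
          sel <- fam$freqs >= cfg$bands[[bn]]$lo &
            fam$freqs <= cfg$bands[[bn]]$hi
          bl <- fam$time >= cfg$baseline[1] & fam$time <= cfg$baseline[2]
          db <- vapply(which(sel), function(f) {
            base <- stats::median(med[f, bl], na.rm = TRUE)
            10 * log10(med[f, ] / base)
          }, numeric(length(fam$time)))
          traces[[key]] <- tibble::tibble(
            condition = cond, stream = stream, band = bn,
            array = as.integer(a), time = fam$time,
            db = rowMeans(db))
        }
      }
      if (stream == "total") {
        pc <- fams$lf$per_channel
        if (use_hf) pc <- dplyr::bind_rows(pc, fams$hf$per_channel)
        per_channel[[paste(cond, stream)]] <-
          dplyr::mutate(pc, condition = cond)
      }
    }
  }
  # ---- statistics ------------------------------------------------------
  stat_rows <- list()
  scfg <- cfg$stats
  a_stat <- as.character(cfg$stat_array)
  for (bn in names(fam_of_band)) {
    for (stream in intersect(cfg$streams, c("total", "NPL"))) {
      for (cond in conds) {
        key <- paste(cond, stream, bn, a_stat, sep = ".")
        if (is.null(tensors[[key]])) next
        st <- bootstrap_vs_zero(tensors[[key]], scfg)
        stat_rows[[length(stat_rows) + 1L]] <- dplyr::mutate(
          tidy(st), band = bn, stream = stream,
          comparison = paste0(cond, " vs baseline"),
          family = paste("boot", stream, bn))
      }
      if (length(conds) >= 2) {
        prs <- utils::combn(conds, 2)
        for (j in seq_len(ncol(prs))) {
          c1 <- prs[1, j]; c2 <- prs[2, j]
          t1 <- tensors[[paste(c1, stream, bn, a_stat, sep = ".")]]
          t2 <- tensors[[paste(c2, stream, bn, a_stat, sep = ".")]]
          if (is.null(t1) || is.null(t2)) next
          pcfg <- scfg
          if ("brain" %in% c(c1, c2) && t1$n_trials != t2$n_trials) {
            pcfg$subsample_to <- min(t1$n_trials, t2$n_trials)
          }
          st <- perm_condition(t1, t2, pcfg)
          stat_rows[[length(stat_rows) + 1L]] <- dplyr::mutate(
            tidy(st), band = bn, stream = stream,
            comparison = paste(c1, "vs", c2),
            family = paste("perm", stream, bn))
        }
      }
    }
  }
  if (!is.null(cfg$array_test) && length(per_channel)) {
    pc_all <- dplyr::bind_rows(per_channel)
    for (bn in unique(pc_all$band)) {
      for (cond in conds) {
        sub <- pc_all[pc_all$band == bn & pc_all$condition == cond &
                        pc_all$array %in% cfg$array_test, ]
        if (length(unique(sub$array)) == 2) {
          st <- perm_array(sub$value, sub$array, scfg)
          stat_rows[[length(stat_rows) + 1L]] <- dplyr::mutate(
            tidy(st), band = bn, stream = "total",
            comparison = paste0(cond, ": array ", cfg$array_test[1],
                                " vs ", cfg$array_test[2]),
            family = paste("array", bn))
        }
      }
    }
  }
  stats_tbl <- dplyr::bind_rows(stat_rows)
  if (nrow(stats_tbl)) {
    stats_tbl$p_fdr <- fdr_bh(stats_tbl$p.value, stats_tbl$family)
  }
  # ---- summary CIs from the bootstrap results --------------------------
  summary_tbl <- dplyr::bind_rows(summary_rows)
  structure(list(
    summary = summary_tbl,
    stats = stats_tbl,
    traces = dplyr::bind_rows(traces),
    per_channel = if (length(per_channel)) dplyr::bind_rows(per_channel)
                  else tibble::tibble(),
    tensors = tensors,
    log = list(
      seed = scfg$seed,
      config_hash = rlang::hash(unclass(cfg)),
      n_sessions = length(sessions),
      trials_kept = n_kept, trials_rejected = n_rejected,
      artifact_policy = "rejection only",
      streams = cfg$streams,
      package_version = as.character(utils::packageVersion("alphaloop")))
  ), class = "al_results")
}

#' @export
print.al_results <- function(x, ...) {
  cat(sprintf(
    "<analysis results> %d trials (%d rejected), %d sessions; %s stream(s)\n",
    x$log$trials_kept, x$log$trials_rejected, x$log$n_sessions,
    paste(x$log$streams, collapse = "/")))
  print(x$summary)
  invisible(x)
}

# pool al_epochs along trials (same channel sets required)
pool_epochs <- function(parts) {
  if (length(parts) == 1) return(parts[[1]])
  base <- parts[[1]]
  if (!all(vapply(parts, function(p) {
    identical(p$channels$channel, base$channels$channel)
  }, logical(1)))) {
    stop("pool_epochs: sessions must share the same analysis channels")
  }
  base$data <- do.call(abind_first, lapply(parts, `[[`, "data"))
  base$condition <- unlist(lapply(parts, `[[`, "condition"))
  offs <- cumsum(c(0, vapply(parts, function(p) max(p$trial_id), numeric(1))))
  base$trial_id <- unlist(lapply(seq_along(parts), function(i) {
    parts[[i]]$trial_id + offs[i]
  }))
  base
}

abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

subset_epochs <- function(epochs, rows) {
  out <- epochs
  out$data <- epochs$data[rows, , , drop = FALSE]
  out$condition <- epochs$condition[rows]
  out$trial_id <- epochs$trial_id[rows]
  out
}

#' Export a band summary table as tidy CSV
#'
#' @param results An `al_results`.
#' @param path File path for the CSV.
#' @return `path`, invisibly.
#' @export
write_band_summary <- function(results, path) {
  stopifnot(inherits(results, "al_results"))
  utils::write.csv(results$summary, path, row.names = FALSE)
  invisible(path)
}

#' Export the statistics table as tidy CSV
#'
#' One row per test: scheme, band, comparison, estimate, confidence bounds,
#' uncorrected and FDR-corrected p-values, draw counts and seed.
#'
#' @inheritParams write_band_summary
#' @export
write_stats_table <- function(results, path) {
  stopifnot(inherits(results, "al_results"))
  utils::write.csv(results$stats, path, row.names = FALSE)
  invisible(path)
}
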