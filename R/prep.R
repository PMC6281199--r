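#' Epoch a session around stimulation events
#'
#' Cuts fixed windows around every stimulation onset or offset. Window
#' endpoints are half-open at sample resolution, `[t + w1, t + w2)`, so a
#' 10 s window at 1000 Hz yields exactly 10000 samples and the alignment
#' sample is not double-counted. Events whose window falls partly outside the
#' recording are dropped; the dropped count is recorded in the result and
#' reported with a message.
#'
#' @param session An `al_session`.
#' @param align `"onset"` or `"offset"`.
#' @param window Numeric `c(start, end)` in seconds relative to the event.
#' @param channels Integer channel numbers to keep (default: all channels;
#'   see [select_channels()]).
#' @param trials Optional trial ids to keep (e.g. from [reject_trials()]).
#' @return An `al_epochs` object: `data` (trials x channels x time, uV),
#'   `time` (s, relative to the event), `fs`, `condition`, `trial_id`,
#'   `channels` (map subset), `align`, `provenance`.
#' @export
epoch_events <- function(session, align = c("onset", "offset"),
                         window = c(-5, 5), channels = NULL, trials = NULL) {
  align <- match.arg(align)
  fs <- session$fs
  ev <- session$events
  ev <- ev[ev$kind == if (align == "onset") "stim_on" else "stim_off", ]
  if (!is.null(trials)) ev <- ev[ev$trial_id %in% trials, ]
  if (nrow(ev) == 0) stop("epoch_events: no events to epoch")
  if (is.null(channels)) channels <- session$map$channel
  chan_idx <- match(channels, session$map$channel)
  ns <- ncol(session$signals)
  n_t <- round((window[2] - window[1]) * fs)
  start <- round(ev$time_s * fs) + round(window[1] * fs) + 1L
  ok <- start >= 1 & (start + n_t - 1L) <= ns
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(sprintf("epoch_events: dropped %d event(s) outside the recording",
                    dropped))
  }
  ev <- ev[ok, ]; start <- start[ok]
  if (nrow(ev) == 0) stop("epoch_events: all events fall outside the recording")
  data <- array(NA_real_, dim = c(nrow(ev), length(chan_idx), n_t))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- session$signals[chan_idx, start[i]:(start[i] + n_t - 1L),
                                   drop = FALSE]
  }
  structure(list(
    data = data,
    time = window[1] + (seq_len(n_t) - 1L) / fs,
    fs = fs,
    condition = ev$condition,
    trial_id = ev$trial_id,
    channels = session$map[chan_idx, ],
    align = align,
    n_dropped = dropped,
    provenance = c(paste0(align, "-aligned"), "rejection only")
  ), class = "al_epochs")
}

#' @export
print.al_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs (%s)> %d trials x %d channels x %d samples @ %g Hz\n",
              paste(x$align, collapse = "+"), d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Reject trials by stimulation duration
#'
#' Keeps trials whose marked onset-to-offset elapsed time does not exceed the
#' limit: 11 s for in vivo sessions and 20 s for in vitro sessions, where the
#' amplifier takes longer to desaturate.
#'
#' @param onsets Either a numeric vector of onset times (s) or a session /
#'   event tibble, in which case `offsets` is ignored and times are taken
#'   from the event table (paired by `trial_id`).
#' @param offsets Numeric vector of offset times (s), paired with `onsets`.
#' @param max_duration Maximum allowed elapsed time in seconds.
#' @return Integer vector of kept trial ids (positions for vector input).
#' @examples
#' reject_trials(c(0, 60, 120), c(8.9, 70.7, 131.2), max_duration = 11)
#' @export
reject_trials <- function(onsets, offsets = NULL, max_duration = 11) {
  if (inherits(onsets, "al_session")) onsets <- onsets$events
  if (is.data.frame(onsets)) {
    ev <- onsets
    on <- ev[ev$kind == "stim_on", c("trial_id", "time_s")]
    off <- ev[ev$kind == "stim_off", c("trial_id", "time_s")]
    if (!setequal(on$trial_id, off$trial_id)) {
      stop("reject_trials: unpaired events (trial ids differ between on and off)")
    }
    off <- off[match(on$trial_id, off$trial_id), ]
    keep <- (off$time_s - on$time_s) <= max_duration
    return(on$trial_id[keep])
  }
  if (length(onsets) != length(offsets)) {
    stop("reject_trials: unpaired events (onset/offset lengths differ)")
  }
  which((offsets - onsets) <= max_duration)
}

#' Select analysis channels
#'
#' By default removes the controller channel and its bipolar reference, plus
#' channels known to be non-functioning, before analysis. Optionally restricts
#' to a single array.
#'
#' @param session An `al_session` (or a channel-map tibble).
#' @param drop_controller Drop the controller pair (default `TRUE`).
#' @param drop_bad Drop flagged bad channels (default `TRUE`).
#' @param array Optional array id to restrict to.
#' @return Integer vector of kept channel numbers.
#' @export
select_channels <- function(session, drop_controller = TRUE, drop_bad = TRUE,
                            array = NULL) {
  map <- if (inherits(session, "al_session")) session$map else session
  keep <- rep(TRUE, nrow(map))
  if (drop_controller) keep <- keep & !map$controller & !map$controller_ref
  if (drop_bad) keep <- keep & !map$bad
  if (!is.null(array)) keep <- keep & map$array %in% array
  if (!any(keep)) stop("select_channels: selection leaves no channels")
  map$channel[keep]
}

#' Concatenate pre-onset and post-offset voltage epochs
#'
#' Per trial, joins the `[-5, 0)` s segment of the onset-aligned epoch with
#' the `[0, +5)` s segment of the offset-aligned epoch, excising the
#' stimulation period and re-indexing to a continuous 10 s axis on which
#' post-offset `t = 0` is the offset event. Trials are paired by id.
#'
#' @param onset_epochs,offset_epochs `al_epochs` aligned to onsets / offsets.
#' @return An `al_epochs` object with provenance `"concatenated"`.
#' @export
build_prepost <- function(onset_epochs, offset_epochs) {
  stopifnot(inherits(onset_epochs, "al_epochs"),
            inherits(offset_epochs, "al_epochs"))
  if (!setequal(onset_epochs$trial_id, offset_epochs$trial_id)) {
    stop("build_prepost: unmatched trial ids between onset and offset epochs")
  }
  ord <- match(onset_epochs$trial_id, offset_epochs$trial_id)
  pre_idx <- which(onset_epochs$time < 0)
  post_idx <- which(offset_epochs$time >= 0)
  data <- array(NA_real_, dim = c(dim(onset_epochs$data)[1],
                                  dim(onset_epochs$data)[2],
                                  length(pre_idx) + length(post_idx)))
  data[, , seq_along(pre_idx)] <- onset_epochs$data[, , pre_idx, drop = FALSE]
  data[, , length(pre_idx) + seq_along(post_idx)] <-
    offset_epochs$data[ord, , post_idx, drop = FALSE]
  structure(list(
    data = data,
    time = c(onset_epochs$time[pre_idx], offset_epochs$time[post_idx]),
    fs = onset_epochs$fs,
    condition = onset_epochs$condition,
    trial_id = onset_epochs$trial_id,
    channels = onset_epochs$channels,
    align = c("onset", "offset"),
    provenance = c("concatenated", "rejection only")
  ), class = "al_epochs")
}
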