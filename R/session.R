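#' Electrode channel map
#'
#' Builds the per-channel geometry/metadata table for one or more implanted
#' arrays. The default layout mirrors a 96-electrode "Utah" style array:
#' a 10 x 10 grid with the four corner positions removed. Smaller rectangular
#' grids are supported for scaled-down synthetic studies.
#'
#' @param n_arrays Number of arrays (1-3); arrays are numbered from 1.
#' @param layout Either `"utah96"` (10 x 10 minus corners, 96 electrodes) or
#'   an integer vector `c(nrow, ncol)` for a full rectangular grid.
#' @param controller Grid position `c(row, col)` of the controller electrode
#'   on array 1; its bipolar reference is the horizontally adjacent electrode
#'   at `c(row, col + 1)`.
#' @param bad Integer vector of channel numbers flagged as non-functioning.
#' @return A tibble with columns `channel`, `array`, `row`, `col`,
#'   `controller`, `controller_ref`, `bad`.
#' @examples
#' map <- channel_map()
#' nrow(map)  # 288 electrodes across three arrays
#' @export
channel_map <- function(n_arrays = 3, layout = "utah96",
                        controller = NULL, bad = integer(0)) {
  if (identical(layout, "utah96")) {
    grid <- expand.grid(col = 1:10, row = 1:10)[, c("row", "col")]
    corners <- (grid$row %in% c(1, 10)) & (grid$col %in% c(1, 10))
    grid <- grid[!corners, ]
    if (is.null(controller)) controller <- c(5, 5)
  } else {
    stopifnot(is.numeric(layout), length(layout) == 2)
    grid <- expand.grid(col = seq_len(layout[2]), row = seq_len(layout[1]))
    grid <- grid[, c("row", "col")]
    if (is.null(controller)) controller <- c(1, 1)
  }
  per <- nrow(grid)
  map <- tibble::tibble(
    channel = seq_len(per * n_arrays),
    array = rep(seq_len(n_arrays), each = per),
    row = rep(grid$row, n_arrays),
    col = rep(grid$col, n_arrays),
    controller = FALSE, controller_ref = FALSE, bad = FALSE
  )
  ctl <- which(map$array == 1 & map$row == controller[1] &
                 map$col == controller[2])
  ref <- which(map$array == 1 & map$row == controller[1] &
                 map$col == controller[2] + 1)
  if (length(ctl) != 1 || length(ref) != 1) {
    stop("channel_map: controller position (and its right neighbour) must ",
         "exist on array 1")
  }
  map$controller[ctl] <- TRUE
  map$controller_ref[ref] <- TRUE
  map$bad[map$channel %in% bad] <- TRUE
  attr(map, "layout") <- if (identical(layout, "utah96")) "utah96" else layout
  map
}

#' Construct a recording session object
#'
#' The in-memory container for one continuous multi-channel recording:
#' single-ended electrode signals, the clean bipolar controller trace, the
#' channel map, and the stimulation event table.
#'
#' @param signals Numeric matrix, channels x samples, in microvolts.
#' @param controller Numeric vector (length = samples): the bipolar-referenced
#'   controller-channel trace (free of stimulation saturation).
#' @param fs Sampling rate in Hz.
#' @param map Channel map tibble (see [channel_map()]).
#' @param events Event tibble with columns `time_s`, `kind`
#'   (`"stim_on"`/`"stim_off"`), `condition` (`"open"`, `"closed"`,
#'   `"brain"`), `block`, `trial_id`.
#' @param kind `"in_vivo"` or `"in_vitro"` (selects e.g. the trial-rejection
#'   limit downstream).
#' @param ground_truth Optional list recording injected effects and generator
#'   parameters (synthetic sessions).
#' @return An object of class `al_session`.
#' @export
new_session <- function(signals, controller, fs, map, events,
                        kind = c("in_vivo", "in_vitro"), ground_truth = NULL) {
  kind <- match.arg(kind)
  s <- structure(list(signals = signals, controller = controller, fs = fs,
                      map = map, events = events, kind = kind,
                      ground_truth = ground_truth),
                 class = "al_session")
  validate_session(s)
  s
}

#' Validate a session against the container schema
#'
#' Checks every structural invariant and reports all violations at once.
#'
#' @param session An `al_session`.
#' @return The session, invisibly, if valid; otherwise an error listing every
#'   failed invariant.
#' @export
validate_session <- function(session) {
  bad <- character(0)
  m <- session$map
  ev <- session$events
  if (!is.matrix(session$signals)) {
    bad <- c(bad, "signals must be a channels x samples matrix")
  } else {
    if (nrow(session$signals) != nrow(m)) {
      bad <- c(bad, sprintf("channel count mismatch: %d signal rows vs %d map rows",
                            nrow(session$signals), nrow(m)))
    }
    if (length(session$controller) != ncol(session$signals)) {
      bad <- c(bad, "controller trace length differs from signal samples")
    }
  }
  if (sum(m$controller) != 1 || sum(m$controller_ref) != 1) {
    bad <- c(bad, "map must flag exactly one controller and one reference channel")
  } else {
    a <- m[m$controller, ]; b <- m[m$controller_ref, ]
    if (a$array != b$array || abs(a$row - b$row) + abs(a$col - b$col) != 1) {
      bad <- c(bad, "controller pair must be adjacent on the same array")
    }
  }
  if (identical(attr(m, "layout"), "utah96") &&
      any(table(m$array) != 96)) {
    bad <- c(bad, "utah96 layout requires 96 electrodes per array")
  }
  need_ev <- c("time_s", "kind", "condition", "block", "trial_id")
  if (!all(need_ev %in% names(ev))) {
    bad <- c(bad, paste("event table must have columns:",
                        paste(need_ev, collapse = ", ")))
  } else {
    if (is.unsorted(ev$time_s, strictly = TRUE)) {
      bad <- c(bad, "event times must be strictly increasing")
    }
    if (!all(ev$kind %in% c("stim_on", "stim_off"))) {
      bad <- c(bad, "event kind must be stim_on or stim_off")
    }
    if (!all(ev$condition %in% c("open", "closed", "brain"))) {
      bad <- c(bad, "event condition must be open, closed or brain")
    }
    for (id in unique(ev$trial_id)) {
      k <- ev$kind[ev$trial_id == id]
      if (length(k) != 2 || k[1] != "stim_on" || k[2] != "stim_off") {
        bad <- c(bad, sprintf(
          "trial %s must have one stim_on followed by one stim_off", id))
      }
    }
  }
  if (length(bad)) {
    stop("invalid session:\n  - ", paste(bad, collapse = "\n  - "))
  }
  invisible(session)
}

#' @export
print.al_session <- function(x, ...) {
  cat(sprintf("<session (%s)> %d channels x %d samples @ %g Hz, %d trials\n",
              x$kind, nrow(x$signals), ncol(x$signals), x$fs,
              length(unique(x$events$trial_id))))
  invisible(x)
}

#' Write / read a session container on disk
#'
#' The on-disk container is a directory holding `meta.json` (sample rate,
#' units, kind, matrix geometry, byte order), `map.csv`, `events.csv`,
#' `signals.bin` and `controller.bin` (little-endian float64, column-major
#' channels x samples), and optionally `ground_truth.json`. The round trip is
#' bit-exact for the signal matrices and field-for-field for metadata.
#'
#' @param session An `al_session`.
#' @param path Directory to create/overwrite.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed, validated `al_session`.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "alphaloop-session", version = 1L,
               fs = session$fs, units = "uV", kind = session$kind,
               n_channels = nrow(session$signals),
               n_samples = ncol(session$signals),
               dtype = "float64", byte_order = "little",
               layout = "column_major_channels_x_samples",
               map_layout = attr(session$map, "layout"))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(session$map, file.path(path, "map.csv"), row.names = FALSE)
  utils::write.csv(session$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  con <- file(file.path(path, "signals.bin"), "wb")
  writeBin(as.vector(session$signals), con, size = 8, endian = "little")
  close(con)
  con <- file(file.path(path, "controller.bin"), "wb")
  writeBin(as.numeric(session$controller), con, size = 8, endian = "little")
  close(con)
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth,
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  if (!identical(meta$format, "alphaloop-session")) {
    stop("read_session: not an alphaloop session container: ", path)
  }
  nch <- meta$n_channels; ns <- meta$n_samples
  con <- file(file.path(path, "signals.bin"), "rb")
  x <- readBin(con, "double", n = nch * ns + 1, size = 8, endian = "little")
  close(con)
  if (length(x) != nch * ns) {
    stop(sprintf(
      "read_session: signal matrix length mismatch: expected %d values, found %d",
      nch * ns, length(x)))
  }
  signals <- matrix(x, nrow = nch)
  con <- file(file.path(path, "controller.bin"), "rb")
  controller <- readBin(con, "double", n = ns + 1, size = 8, endian = "little")
  close(con)
  if (length(controller) != ns) {
    stop("read_session: controller trace length mismatch")
  }
  map <- tibble::as_tibble(utils::read.csv(file.path(path, "map.csv")))
  lay <- meta$map_layout
  attr(map, "layout") <- if (is.character(lay)) lay else unlist(lay)
  events <- tibble::as_tibble(utils::read.csv(file.path(path, "events.csv")))
  gt_path <- file.path(path, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else NULL
  new_session(signals, controller, meta$fs, map, events, kind = meta$kind,
              ground_truth = gt)
}
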