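#' Stochastic alpha-oscillator plant
#'
#' The simulated "brain" is a damped harmonic oscillator (an AR(2) process in
#' discrete time) driven by white noise, superposed on a 1/f background.
#' Feedback current enters as additive drive on the oscillator's velocity
#' equation (implemented as a differentiator normalized to unit gain and a
#' +90 degree lead at the natural frequency), so a stimulation waveform in
#' phase with the recorded oscillation pumps energy into it — the
#' constructive-interference regime. The electrode/tissue transfer is
#' identity; the conversion from current to effective drive is absorbed
#' into `coupling`.
#'
#' @param natural_freq Oscillator natural frequency in Hz (default 11,
#'   inside the alpha band).
#' @param damping Damping ratio in (0, 1) (default 0.012; the post-stimulation
#'   amplitude decay time constant is `1/(damping * 2 * pi * natural_freq)`,
#'   ~1.2 s at defaults, so stimulation-built amplitude largely dissipates
#'   within about a second of offset).
#' @param noise_sd Innovation SD in microvolt-equivalent drive per sample at
#'   1000 Hz (default 1; the resonance amplifies this to an oscillator RMS of
#'   roughly 250 uV at the default damping).
#' @param coupling Drive in microvolts per milliampere of applied stimulation
#'   current (signed). The default 0.0296 gives a resonant loop gain of about
#'   0.5 with the default filter/loop configuration (see [loop_gain()]),
#'   safely inside the stability margin.
#' @param background_exponent Spectral slope of the additive 1/f background.
#' @param background_rms RMS of the 1/f background in microvolts.
#' @return An `al_plant_config` object.
#' @export
plant_config <- function(natural_freq = 11, damping = 0.012, noise_sd = 1,
                         coupling = 0.0296, background_exponent = 1,
                         background_rms = 100) {
  if (damping <= 0 || damping >= 1) stop("plant_config: damping must be in (0,1)")
  if (natural_freq <= 5 || natural_freq >= 30) {
    stop("plant_config: natural_freq must lie in (5, 30) Hz")
  }
  if (noise_sd <= 0) stop("plant_config: noise_sd must be > 0")
  structure(list(natural_freq = natural_freq, damping = damping,
                 noise_sd = noise_sd, coupling = coupling,
                 background_exponent = background_exponent,
                 background_rms = background_rms),
            class = "al_plant_config")
}

# AR(2) coefficients of the discretized oscillator
plant_ar2 <- function(plant, fs) {
  wn <- 2 * pi * plant$natural_freq
  r <- exp(-plant$damping * wn / fs)
  th <- wn * sqrt(1 - plant$damping^2) / fs
  c(2 * r * cos(th), -r^2)
}

# |drive -> output| gain of the discrete plant at frequency f
plant_gain <- function(plant, f, fs) {
  cc <- plant_ar2(plant, fs)
  z <- exp(-2i * pi * f / fs)
  Mod(1 / (1 - cc[1] * z - cc[2] * z^2))
}

# first difference normalized to unit gain (and +90 degree lead) at f0
diff_norm_scale <- function(fs, f0) {
  1 / (2 * sin(pi * f0 / fs))
}
diff_norm <- function(x, fs, f0) {
  diff_norm_scale(fs, f0) * c(0, diff(x))
}

#' Small-signal loop gain of the feedback chain
#'
#' Magnitude of plant x preamp x filter x stimulator x coupling around the
#' loop at frequency `f`. Values below 1 at the frequency where the loop
#' phase is a multiple of 360 degrees keep the positive-feedback loop stable.
#'
#' @param plant An `al_plant_config`.
#' @param spec An `al_filter_spec`.
#' @param loop An `al_loop_config`.
#' @param f Frequency in Hz (default: the plant natural frequency).
#' @param fs Sampling rate (default from `loop`).
#' @return Dimensionless gain.
#' @export
loop_gain <- function(plant, spec, loop, f = plant$natural_freq,
                      fs = loop$sample_rate) {
  plant_gain(plant, f, fs) * loop$preamp_gain *
    Mod(mfb_biquad_response(spec, fs, f)) *
    (loop$stim_gain * 1e3) * abs(plant$coupling)
}

#' Coupling calibrated to a target resonant loop gain
#'
#' @inheritParams loop_gain
#' @param target_gain Desired loop gain at `f` (default 0.5).
#' @return Coupling value (uV per mA) for [plant_config()].
#' @export
calibrate_coupling <- function(plant, spec, loop, target_gain = 0.5,
                               f = plant$natural_freq, fs = loop$sample_rate) {
  unit <- plant_config(plant$natural_freq, plant$damping, plant$noise_sd,
                       coupling = 1,
                       background_exponent = plant$background_exponent,
                       background_rms = plant$background_rms)
  target_gain / loop_gain(unit, spec, loop, f = f, fs = fs)
}

#' Trial schedule
#'
#' Stimulation trials of nominally 10 s followed by rest, in blocks of equal
#' condition, with a longer rest between blocks. Manually timed onsets and
#' offsets are emulated by drawing each trial's marked duration uniformly
#' from the jitter range.
#'
#' @param stim_duration Nominal stimulation duration (s).
#' @param jitter Range (s) of realized onset-to-offset durations (must
#'   contain the nominal duration); default `c(7.74, 10.74)`.
#' @param rest_duration Rest after each trial (s, default 40).
#' @param trials_per_block Trials per condition block (default 10).
#' @param inter_block_rest Additional rest between blocks (s, default 120).
#' @param block_conditions Condition label per block, in
#'   `c("open", "closed", "brain")`; the executed order is shuffled by the
#'   session seed.
#' @param seed Optional schedule-specific seed for the block order (otherwise
#'   the session seed is used).
#' @return An `al_schedule` object.
#' @export
trial_schedule <- function(stim_duration = 10, jitter = c(7.74, 10.74),
                           rest_duration = 40, trials_per_block = 10,
                           inter_block_rest = 120,
                           block_conditions = rep(c("open", "closed", "brain"), 2),
                           seed = NULL) {
  stopifnot(stim_duration > 0, rest_duration > 0, trials_per_block >= 1)
  if (jitter[1] > stim_duration || jitter[2] < stim_duration) {
    stop("trial_schedule: jitter range must contain the nominal duration")
  }
  if (!all(block_conditions %in% c("open", "closed", "brain"))) {
    stop("trial_schedule: unknown condition label")
  }
  structure(list(stim_duration = stim_duration, jitter = jitter,
                 rest_duration = rest_duration,
                 trials_per_block = trials_per_block,
                 inter_block_rest = inter_block_rest,
                 block_conditions = block_conditions, seed = seed),
            class = "al_schedule")
}

# Realize a schedule into trial times. Returns a tibble with onset, offset
# (the *marked* offset used for analysis), stim_end (actual end of current
# flow), condition, block, trial_id, plus attributes lead_in and total
# duration. For in vitro sessions the amplifier settles slowly, so marked
# durations are drawn from settle_range instead of the jitter range.
schedule_events <- function(schedule, seed, kind = "in_vivo",
                            lead_in = 8, tail = 8,
                            settle_range = c(12, 21), settle_in_vivo = 0.3) {
  withr::with_seed(if (!is.null(schedule$seed)) schedule$seed else seed, {
    conds <- sample(schedule$block_conditions)
    rows <- list()
    t <- lead_in
    id <- 0L
    for (b in seq_along(conds)) {
      for (k in seq_len(schedule$trials_per_block)) {
        id <- id + 1L
        dur <- stats::runif(1, schedule$jitter[1], schedule$jitter[2])
        if (kind == "in_vitro") {
          marked <- stats::runif(1, settle_range[1], settle_range[2])
          stim_end <- t + schedule$stim_duration
          offset <- t + marked
        } else {
          offset <- t + dur
          stim_end <- max(t + 0.5, offset - settle_in_vivo)
        }
        rows[[id]] <- tibble::tibble(onset = t, offset = offset,
                                     stim_end = stim_end,
                                     condition = conds[b], block = b,
                                     trial_id = id)
        t <- offset + schedule$rest_duration
      }
      t <- t + schedule$inter_block_rest
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "duration") <- t - schedule$inter_block_rest + tail
    out
  })
}

# events tibble (long format) from realized trials
events_from_trials <- function(trials) {
  long <- tibble::tibble(
    time_s = c(rbind(trials$onset, trials$offset)),
    kind = rep(c("stim_on", "stim_off"), nrow(trials)),
    condition = rep(trials$condition, each = 2),
    block = rep(trials$block, each = 2),
    trial_id = rep(trials$trial_id, each = 2)
  )
  long[order(long$time_s), ]
}

#' Simulate the free-running or driven oscillator plant
#'
#' @param plant An `al_plant_config`.
#' @param input Optional stimulation current series in mA (same `fs` and
#'   length as the output); `NULL` simulates the free-running plant.
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; identical seeds (and inputs) give identical
#'   traces.
#' @return Numeric voltage series (uV): oscillator plus 1/f background.
#' @export
simulate_plant <- function(plant, input = NULL, duration, fs = 1000, seed = 1) {
  stopifnot(inherits(plant, "al_plant_config"), duration > 0)
  n <- round(duration * fs)
  if (!is.null(input) && length(input) != n) {
    stop("simulate_plant: input length must match duration * fs")
  }
  cc <- plant_ar2(plant, fs)
  withr::with_seed(seed, {
    innov <- stats::rnorm(n, 0, plant$noise_sd * sqrt(fs / 1000))
    bg <- pink_noise(n, fs, plant$background_exponent, plant$background_rms)
    drive <- if (is.null(input)) 0 else {
      plant$coupling * diff_norm(input, fs, plant$natural_freq)
    }
    osc <- stats::filter(innov + drive, cc, method = "recursive")
    as.numeric(osc) + bg
  })
}

#' Stimulator command for one trial
#'
#' Builds the command-voltage series for a given condition: `closed` applies
#' the causal discrete filter chain to the concurrent plant output, `open` is
#' a fixed 11.5 Hz sinusoid, `brain` is a previously recorded band-pass
#' filtered neural waveform replayed open-loop. All are clipped to the
#' command limit.
#'
#' @param condition `"open"`, `"closed"` or `"brain"`.
#' @param plant_output Concurrent plant/controller trace in uV.
#' @param spec An `al_filter_spec`.
#' @param loop An `al_loop_config`.
#' @param replay For `"brain"`: previously recorded controller trace (uV), at
#'   least as long as the trial.
#' @param fs Sampling rate (Hz).
#' @param open_amp,open_freq Amplitude (V) and frequency (Hz) of the open-loop
#'   sinusoid (defaults 0.4 V, 11.5 Hz).
#' @return Command-voltage series (V), same length as `plant_output`.
#' @export
make_stim_command <- function(condition, plant_output, spec, loop,
                              replay = NULL, fs = loop$sample_rate,
                              open_amp = 0.4, open_freq = 11.5) {
  n <- length(plant_output)
  lim <- loop$command_limit
  cmd <- switch(condition,
    closed = apply_filter(loop$preamp_gain * plant_output, fs, spec, loop),
    open = open_amp * sin(2 * pi * open_freq * (seq_len(n) - 1) / fs),
    brain = {
      if (is.null(replay) || length(replay) < n) {
        stop("make_stim_command: brain condition needs a replay trace at ",
             "least as long as the trial")
      }
      apply_filter(loop$preamp_gain * replay[seq_len(n)], fs, spec, loop)
    },
    stop("make_stim_command: unknown condition: ", condition)
  )
  pmin(pmax(cmd, -lim), lim)
}

#' Simulate a full closed-loop stimulation session
#'
#' Runs the per-sample feedback loop over an entire realized schedule:
#' during `closed` trials the command is the filtered, delayed, clipped
#' feedback of the concurrent plant output; `open` trials replay a fixed
#' 11.5 Hz sinusoid; `brain` trials replay a band-pass-filtered plant trace
#' simulated with a different seed (a "previous day"). Electrode channels
#' are correlated copies of the controller source with channel noise and a
#' saturation artifact during stimulation; the bipolar controller trace
#' stays clean.
#'
#' @param plant An `al_plant_config`.
#' @param spec An `al_filter_spec`.
#' @param loop An `al_loop_config`.
#' @param schedule An `al_schedule`.
#' @param seed Integer seed (drives the block order, jitter, noise).
#' @param map Channel map (default: the full three-array 96-electrode map;
#'   smaller maps cut memory for scaled studies).
#' @param fs Sampling rate (default from `loop`).
#' @param open_amp,open_freq Open-loop sinusoid parameters.
#' @return An `al_session` with ground truth recording the loop parameters.
#' @export
run_session <- function(plant, spec, loop, schedule, seed,
                        map = channel_map(), fs = loop$sample_rate,
                        open_amp = 0.4, open_freq = 11.5) {
  trials <- schedule_events(schedule, seed, kind = "in_vivo")
  n <- round(attr(trials, "duration") * fs)
  stim_mask <- integer(n)
  ext_mask <- integer(n)
  ext_cmd <- numeric(n)
  need_brain <- any(trials$condition == "brain")
  replay_cmd <- NULL
  if (need_brain) {
    rep_trace <- simulate_plant(plant, NULL,
                                duration = max(trials$stim_end - trials$onset) + 1,
                                fs = fs, seed = seed + 1003L)
    replay_cmd <- apply_filter(loop$preamp_gain * rep_trace, fs, spec, loop)
  }
  for (i in seq_len(nrow(trials))) {
    i0 <- round(trials$onset[i] * fs) + 1L
    i1 <- round(trials$stim_end[i] * fs)
    stim_mask[i0:i1] <- 1L
    len <- i1 - i0 + 1L
    if (trials$condition[i] == "open") {
      ext_mask[i0:i1] <- 1L
      ext_cmd[i0:i1] <- pmin(pmax(
        open_amp * sin(2 * pi * open_freq * (seq_len(len) - 1) / fs),
        -loop$command_limit), loop$command_limit)
    } else if (trials$condition[i] == "brain") {
      ext_mask[i0:i1] <- 1L
      ext_cmd[i0:i1] <- replay_cmd[seq_len(len)]
    }
  }
  cc <- plant_ar2(plant, fs)
  sim <- withr::with_seed(seed, {
    innov <- stats::rnorm(n, 0, plant$noise_sd * sqrt(fs / 1000))
    closed_loop_cpp(innov, cc[1], cc[2], mfb_biquad(spec, fs),
                    loop$preamp_gain, round(loop$digital_delay * fs),
                    loop$command_limit, loop$polarity,
                    (loop$stim_gain * 1e3) * plant$coupling,
                    diff_norm_scale(fs, plant$natural_freq),
                    stim_mask, ext_cmd, ext_mask)
  })
  bg <- withr::with_seed(seed + 1L, {
    pink_noise(n, fs, plant$background_exponent, plant$background_rms)
  })
  src <- sim$output + bg
  signals <- withr::with_seed(seed + 2L, {
    build_channels(src, map, fs, trials,
                   noise = noise_params(), kind = "in_vivo")
  })
  new_session(signals, controller = src, fs = fs, map = map,
              events = events_from_trials(trials), kind = "in_vivo",
              ground_truth = list(
                generator = "loop_sim",
                loop_phase_at_fn = loop_phase(spec, loop, plant$natural_freq),
                loop_gain = loop_gain(plant, spec, loop, fs = fs),
                polarity = loop$polarity, seed = seed))
}
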