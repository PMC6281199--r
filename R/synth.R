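#' Noise and artifact parameters for the synthetic generator
#'
#' Microvolt units throughout. The shared alpha rhythm is narrow-band
#' filtered Gaussian noise (not a pure sinusoid), so injected effects are
#' broad-band within the alpha range. The amplitude split (alpha ~200 uV RMS
#' over a ~100 uV 1/f background) puts composite signal levels on the
#' few-hundred-microvolt scale expected of cortical LFP and keeps the
#' in-band background small, so multiplicative effects on the rhythm are
#' recovered with little dilution.
#'
#' @param alpha_rms RMS (uV) of the per-channel alpha rhythm.
#' @param alpha_band Band (Hz) of the rhythm (default `c(8, 15)`).
#' @param alpha_share Fraction of alpha *power* shared across an array's
#'   electrodes (default 0.3; field coherence across a few millimetres of
#'   cortex falls off with distance, and most electrode pairs on a
#'   multi-millimetre grid are far apart). The remainder is electrode-private
#'   narrow-band noise. Injected effects scale shared and private parts
#'   alike.
#' @param background_rms RMS (uV) of the per-channel 1/f background.
#' @param background_exponent Spectral exponent of the background.
#' @param channel_noise_rms RMS (uV) of per-channel white sensor noise.
#' @param channel_gain_sd SD of the per-channel gain on the shared rhythm.
#' @param rail Amplifier rail (uV) for the saturation artifact.
#' @param recovery_tau Desaturation time constant (s) after current stops.
#' @param effect_ramp Cosine ramp (s) at the edges of injected effects.
#' @param carrier_rms RMS of shared band carriers created when effects target
#'   the beta or hgp band.
#' @param controller_share Fraction of the shared rhythm visible on the
#'   bipolar controller trace.
#' @param n_bad Number of dead channels drawn per session.
#' @return A list of generator parameters.
#' @export
noise_params <- function(alpha_rms = 200, alpha_band = c(8, 15),
                         alpha_share = 0.3,
                         background_rms = 100, background_exponent = 1,
                         channel_noise_rms = 20, channel_gain_sd = 0.1,
                         rail = 5000, recovery_tau = 0.1, effect_ramp = 0.05,
                         carrier_rms = c(beta = 60, hgp = 20),
                         controller_share = 0.3, n_bad = 2) {
  list(alpha_rms = alpha_rms, alpha_band = alpha_band,
       alpha_share = alpha_share,
       background_rms = background_rms,
       background_exponent = background_exponent,
       channel_noise_rms = channel_noise_rms,
       channel_gain_sd = channel_gain_sd, rail = rail,
       recovery_tau = recovery_tau, effect_ramp = effect_ramp,
       carrier_rms = carrier_rms, controller_share = controller_share,
       n_bad = n_bad)
}

#' Ground-truth effect specification
#'
#' Describes a known post-offset band-power perturbation injected by the
#' synthetic generator: on the targeted array, for trials of the given
#' condition, band power is scaled by `10^(effect_db/10)` for `duration`
#' seconds starting `onset_after_offset` seconds after the marked offset.
#'
#' @param condition `"open"`, `"closed"` or `"brain"`.
#' @param array Target array id.
#' @param band `"alpha"`, `"beta"` or `"hgp"`.
#' @param effect_db Effect size in decibels (power scale).
#' @param onset_after_offset Seconds after the marked offset (default 0).
#' @param duration Effect duration in seconds (default 1).
#' @return An `al_effect` object.
#' @export
effect_spec <- function(condition, array, band = "alpha", effect_db,
                        onset_after_offset = 0, duration = 1) {
  if (!band %in% c("alpha", "beta", "hgp")) {
    stop("effect_spec: band must be alpha, beta or hgp")
  }
  if (duration <= 0) stop("effect_spec: duration must be > 0")
  structure(list(condition = condition, array = array, band = band,
                 effect_db = effect_db,
                 onset_after_offset = onset_after_offset,
                 duration = duration),
            class = "al_effect")
}

# 1/f^exponent noise: white noise through a cascade of first-order
# pole/zero shelving sections (poles log-spaced one decade apart, zeros
# offset by exponent/2 decades), normalized to the target RMS.
pink_noise <- function(n, fs, exponent = 1, rms = 1) {
  x <- stats::rnorm(n)
  if (exponent > 0) {
    fp <- c(0.4, 4, 40)
    fz <- fp * 10^(exponent / 2)
    K <- 2 * fs
    sos <- t(vapply(seq_along(fp), function(i) {
      wz <- 2 * pi * fz[i]; wp <- 2 * pi * fp[i]
      a0 <- 1 + K / wp
      c((1 + K / wz) / a0, (1 - K / wz) / a0, 0, (1 - K / wp) / a0, 0)
    }, numeric(5)))
    x <- sos_filter_cpp(sos, x)
  }
  rms * x / stats::sd(x)
}

# Narrow-band Gaussian rhythm: white noise through twice-applied 2nd-order
# Butterworth high-pass (lo) and low-pass (hi) biquads, scaled to rms.
narrowband_noise <- function(n, fs, band, rms) {
  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(2, band[2] / (fs / 2), type = "low")
  sos <- rbind(c(hp$b / hp$a[1], hp$a[-1] / hp$a[1]),
               c(lp$b / lp$a[1], lp$a[-1] / lp$a[1]))
  sos <- rbind(sos, sos)  # apply each biquad twice (4th-order edges)
  x <- sos_filter_cpp(sos, stats::rnorm(n))
  rms * x / stats::sd(x)
}

# Apply saturation artifact in place: clamp to the rail while current flows,
# exponential recovery afterwards.
apply_saturation <- function(x, fs, trials, rail, tau) {
  n <- length(x)
  for (i in seq_len(nrow(trials))) {
    i0 <- round(trials$onset[i] * fs) + 1L
    i1 <- min(n, round(trials$stim_end[i] * fs))
    x[i0:i1] <- rail
    tr <- trials$tau[i] %||% tau
    nrec <- min(n - i1, round(6 * tr * fs))
    if (nrec > 0) {
      x[i1 + seq_len(nrec)] <- x[i1 + seq_len(nrec)] +
        rail * exp(-(seq_len(nrec) / fs) / tr)
    }
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-trial amplitude envelope implementing one effect on a shared component
effect_envelope <- function(env, fs, trials, effect, ramp) {
  g <- 10^(effect$effect_db / 20)
  sel <- trials$condition == effect$condition
  for (tt in which(sel)) {
    t0 <- trials$offset[tt] + effect$onset_after_offset
    t1 <- t0 + effect$duration
    i0 <- round(t0 * fs) + 1L
    i1 <- min(length(env), round(t1 * fs))
    if (i1 < i0) next
    env[i0:i1] <- g
    nr <- round(ramp * fs)
    if (nr > 1) {
      up <- i0 - 1L + seq_len(nr)
      env[up] <- 1 + (g - 1) * (1 - cos(pi * seq_len(nr) / nr)) / 2
      down <- i1 + seq_len(min(nr, length(env) - i1))
      env[down] <- 1 + (g - 1) * (1 + cos(pi * seq_along(down) / nr)) / 2
    }
  }
  env
}

# Shared per-array components -> per-channel single-ended signals with
# saturation; used by both generators (empty `components` for saline).
build_channels <- function(src, map, fs, trials, noise, kind,
                           components = NULL, private_fun = NULL) {
  n <- if (is.null(src)) length(components[[1]])
       else if (is.matrix(src)) ncol(src) else length(src)
  arrays <- sort(unique(map$array))
  if (is.null(components)) {
    components <- list()
    for (a in arrays) components[[as.character(a)]] <- src
  }
  sat_trials <- trials
  if (kind == "in_vitro") {
    sat_trials$tau <- pmax(0.5, (trials$offset - trials$stim_end) / 3)
  } else {
    sat_trials$tau <- rep(noise$recovery_tau, nrow(trials))
  }
  signals <- matrix(0, nrow(map), n)
  gains <- 1 + stats::rnorm(nrow(map), 0, noise$channel_gain_sd)
  for (i in seq_len(nrow(map))) {
    comp <- components[[as.character(map$array[i])]]
    if (!is.null(private_fun)) comp <- comp + private_fun(map$array[i])
    x <- gains[i] * comp +
      pink_noise(n, fs, noise$background_exponent, noise$background_rms) +
      stats::rnorm(n, 0, noise$channel_noise_rms)
    if (map$bad[i]) {
      x <- stats::rnorm(n, 0, 1)
    } else {
      x <- apply_saturation(x, fs, sat_trials, noise$rail, noise$recovery_tau)
    }
    signals[i, ] <- x
  }
  signals
}

#' Generate a synthetic multi-array session with known effects
#'
#' Purely statistical generator (no plant dynamics): every channel is 1/f
#' background plus a shared per-array narrow-band alpha rhythm; during each
#' stimulation period single-ended channels carry a rail-clamped saturation
#' artifact while the bipolar controller trace stays clean; after each marked
#' offset, band power on targeted arrays is scaled by `10^(effect_db/10)` for
#' the stated duration. Dead channels emit flat traces. The injected ground
#' truth is stored on the session for recovery tests.
#'
#' @param effects List of [effect_spec()] objects (may be empty — null
#'   generator).
#' @param schedule An [trial_schedule()].
#' @param map Channel map (default full three-array map).
#' @param noise Generator parameters from [noise_params()].
#' @param seed Integer seed; sessions are bit-reproducible given a seed.
#' @param fs Sampling rate in Hz (default 1000).
#' @param kind `"in_vivo"` or `"in_vitro"` (affects desaturation behaviour).
#' @return An `al_session` with a `ground_truth` record.
#' @export
generate_session <- function(effects = list(), schedule = trial_schedule(),
                             map = channel_map(), noise = noise_params(),
                             seed = 1, fs = 1000, kind = "in_vivo") {
  if (inherits(effects, "al_effect")) effects <- list(effects)
  arrays <- sort(unique(map$array))
  for (e in effects) {
    if (!e$array %in% arrays) {
      stop("generate_session: effect references array ", e$array,
           " absent from the map")
    }
    if (!e$condition %in% schedule$block_conditions) {
      stop("generate_session: effect references condition '", e$condition,
           "' absent from the schedule")
    }
  }
  trials <- schedule_events(schedule, seed, kind = kind)
  n <- round(attr(trials, "duration") * fs)
  bands <- bands_default()
  withr::with_seed(seed, {
    if (noise$n_bad > 0 && !any(map$bad)) {
      ok <- which(!map$controller & !map$controller_ref)
      map$bad[sample(ok, min(noise$n_bad, length(ok)))] <- TRUE
    }
    components <- list(); envs <- list()
    for (a in arrays) {
      alpha_sh <- narrowband_noise(n, fs, noise$alpha_band,
                                   sqrt(noise$alpha_share) * noise$alpha_rms)
      carriers <- 0
      env <- rep(1, n)
      for (e in effects) {
        if (e$array != a) next
        if (e$band == "alpha") {
          env <- effect_envelope(env, fs, trials, e, noise$effect_ramp)
        } else {
          band <- bands[[e$band]]
          carrier <- narrowband_noise(n, fs, c(band$lo, band$hi),
                                      noise$carrier_rms[[e$band]])
          cenv <- effect_envelope(rep(1, n), fs, trials, e, noise$effect_ramp)
          carriers <- carriers + carrier * cenv
        }
      }
      envs[[as.character(a)]] <- env
      components[[as.character(a)]] <- alpha_sh * env + carriers
    }
    private_rms <- sqrt(1 - noise$alpha_share) * noise$alpha_rms
    private_fun <- function(a) {
      envs[[as.character(a)]] *
        narrowband_noise(n, fs, noise$alpha_band, private_rms)
    }
    controller <- noise$controller_share * components[["1"]] +
      pink_noise(n, fs, noise$background_exponent,
                 0.3 * noise$background_rms) +
      stats::rnorm(n, 0, noise$channel_noise_rms)
    signals <- build_channels(NULL, map, fs, trials, noise, kind,
                              components = components,
                              private_fun = private_fun)
    new_session(signals, controller, fs, map, events_from_trials(trials),
                kind = kind,
                ground_truth = list(
                  generator = "synth",
                  effects = lapply(effects, unclass),
                  seed = seed, fs = fs))
  })
}

#' Generate an in vitro saline-control session
#'
#' Same container structure and stimulation schedule as an in vivo session
#' but with no oscillatory component (a saline bath has no endogenous field
#' generators) and a much longer amplifier desaturation: marked offsets fall
#' 12-21 s after onset (median ~16.5 s), so the in vitro trial-rejection
#' limit of 20 s retains most trials while the 11 s in vivo limit rejects
#' the long-settling ones.
#'
#' @inheritParams generate_session
#' @param settle_range Range (s) of onset-to-marked-offset durations.
#' @return An `al_session` of kind `"in_vitro"`.
#' @export
generate_saline_session <- function(schedule = trial_schedule(),
                                    map = channel_map(1),
                                    noise = noise_params(), seed = 1,
                                    fs = 1000, settle_range = c(12, 21)) {
  trials <- schedule_events(schedule, seed, kind = "in_vitro",
                            settle_range = settle_range)
  n <- round(attr(trials, "duration") * fs)
  withr::with_seed(seed, {
    if (noise$n_bad > 0 && !any(map$bad)) {
      ok <- which(!map$controller & !map$controller_ref)
      map$bad[sample(ok, min(noise$n_bad, length(ok)))] <- TRUE
    }
    components <- list()
    for (a in sort(unique(map$array))) {
      components[[as.character(a)]] <- rep(0, n)
    }
    controller <- pink_noise(n, fs, noise$background_exponent,
                             0.3 * noise$background_rms) +
      stats::rnorm(n, 0, noise$channel_noise_rms)
    signals <- build_channels(NULL, map, fs, trials, noise, "in_vitro",
                              components = components)
    new_session(signals, controller, fs, map, events_from_trials(trials),
                kind = "in_vitro",
                ground_truth = list(generator = "saline", seed = seed, fs = fs))
  })
}
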