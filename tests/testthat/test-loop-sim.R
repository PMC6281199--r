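test_that("free-running plant is seed-deterministic with a spectral peak near f_n", {
  pl <- plant_config()
  x1 <- simulate_plant(pl, NULL, 60, fs = 1000, seed = 2)
  x2 <- simulate_plant(pl, NULL, 60, fs = 1000, seed = 2)
  expect_identical(x1, x2)
  sp <- stats::spectrum(stats::ts(x1, frequency = 1000), plot = FALSE,
                        span = 31)
  pk <- sp$freq[which.max(sp$spec)]
  expect_gt(pk, 8); expect_lt(pk, 15)
  expect_lt(abs(pk - pl$natural_freq), 1)
})

test_that("drive in phase with the oscillator state amplifies alpha power", {
  pl <- plant_config()
  x0 <- simulate_plant(pl, NULL, 30, fs = 1000, seed = 11)
  # replay the plant's own (alpha-dominated) trace as stimulation current
  drive <- 0.5 * x0 / stats::sd(x0)
  x1 <- simulate_plant(pl, input = drive, 30, fs = 1000, seed = 11)
  bp <- function(x) {
    stats::var(signal::filtfilt(signal::butter(4, c(8, 15) / 500), x))
  }
  expect_gt(bp(x1), bp(x0))
  # and zero coupling reproduces the free-running trace exactly
  pl0 <- plant_config(coupling = 0)
  expect_identical(simulate_plant(pl0, input = drive, 30, 1000, seed = 11),
                   simulate_plant(pl0, NULL, 30, 1000, seed = 11))
})

test_that("simulate_plant validates the input length", {
  expect_error(simulate_plant(plant_config(), input = rep(0, 10), 1,
                              fs = 1000, seed = 1), "length")
})

test_that("trial schedule invariants and jitter bookkeeping", {
  expect_error(trial_schedule(stim_duration = 10, jitter = c(11, 12)),
               "jitter")
  expect_error(trial_schedule(block_conditions = "sham"), "condition")
  sch <- trial_schedule(trials_per_block = 5,
                        block_conditions = c("open", "closed"))
  tr <- alphaloop:::schedule_events(sch, seed = 3)
  expect_equal(nrow(tr), 10)
  durs <- tr$offset - tr$onset
  expect_true(all(durs >= 7.74 & durs <= 10.74))
})

test_that("stimulation command modes behave as specified", {
  spec <- design_mfb(12, 1.5)
  loop <- loop_config()
  fs <- 1000
  n <- 5000
  plant_out <- simulate_plant(plant_config(), NULL, n / fs, fs, seed = 4)
  # open loop: spectrum concentrated at 11.5 Hz
  cmd <- make_stim_command("open", plant_out, spec, loop)
  sp <- Mod(stats::fft(cmd - mean(cmd)))[2:(n / 2)]
  f_axis <- (1:(n / 2 - 1)) * fs / n
  expect_lt(abs(f_axis[which.max(sp)] - 11.5), 0.25)
  # closed loop with zero plant output is zero
  expect_equal(make_stim_command("closed", rep(0, n), spec, loop), rep(0, n))
  # brain: band-pass filtered replay up to gain/clip
  replay <- simulate_plant(plant_config(), NULL, n / fs, fs, seed = 5)
  cmd_b <- make_stim_command("brain", plant_out, spec, loop, replay = replay)
  expect_equal(cmd_b,
               pmin(pmax(apply_filter(loop$preamp_gain * replay[1:n], fs,
                                      spec, loop),
                         -loop$command_limit), loop$command_limit))
  expect_error(make_stim_command("brain", plant_out, spec, loop),
               "replay")
})

test_that("run_session: bookkeeping, energy bound, determinism", {
  spec <- design_mfb(12, 1.5)
  loop <- loop_config()
  sch <- trial_schedule(trials_per_block = 10, rest_duration = 11,
                        inter_block_rest = 2,
                        block_conditions = c("open", "closed"))
  m <- channel_map(1, layout = c(2, 2), controller = c(1, 1))
  s1 <- run_session(plant_config(), spec, loop, sch, seed = 6, map = m)
  # 2 blocks x 10 trials -> exactly 20 (on, off) pairs
  expect_equal(sum(s1$events$kind == "stim_on"), 20)
  expect_equal(sum(s1$events$kind == "stim_off"), 20)
  expect_setequal(unique(s1$events$condition), c("open", "closed"))
  validate_session(s1)
  s2 <- run_session(plant_config(), spec, loop, sch, seed = 6, map = m)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$controller, s2$controller)
  expect_identical(s1$events, s2$events)
})

test_that("command never exceeds the limit even at high loop gain", {
  spec <- design_mfb(12, 1.5)
  loop <- loop_config(command_limit = 0.5)
  pl <- plant_config()
  pl$coupling <- calibrate_coupling(pl, spec, loop, target_gain = 0.9)
  sch <- trial_schedule(trials_per_block = 3, rest_duration = 11,
                        inter_block_rest = 2, block_conditions = "closed")
  m <- channel_map(1, layout = c(2, 2), controller = c(1, 1))
  tr <- alphaloop:::schedule_events(sch, seed = 9)
  n <- round(attr(tr, "duration") * 1000)
  mask <- integer(n)
  for (i in seq_len(nrow(tr))) {
    mask[(round(tr$onset[i] * 1000) + 1):round(tr$stim_end[i] * 1000)] <- 1L
  }
  cc <- alphaloop:::plant_ar2(pl, 1000)
  sim <- withr::with_seed(9, closed_loop_cpp(
    stats::rnorm(n, 0, pl$noise_sd), cc[1], cc[2],
    alphaloop:::mfb_biquad(spec, 1000), loop$preamp_gain, 42,
    loop$command_limit, 1, (loop$stim_gain * 1e3) * pl$coupling,
    alphaloop:::diff_norm_scale(1000, pl$natural_freq),
    mask, numeric(n), integer(n)))
  expect_lte(max(abs(sim$command)), loop$command_limit)
  expect_true(all(is.finite(sim$output)))
})
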