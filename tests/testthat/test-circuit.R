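test_that("MFB design realizes the requested f0, Q and gain from components", {
  spec <- design_mfb(12, 1.5, A0_mag = 1, C = 100e-9)
  rederived <- mfb_spec(spec$R1, spec$R2, spec$R3, spec$C)
  expect_equal(rederived$f0, 12, tolerance = 1e-9)
  expect_equal(rederived$Q, 1.5, tolerance = 1e-9)
  expect_equal(abs(rederived$A0), 1, tolerance = 1e-9)
  expect_lt(spec$A0, 0)  # naturally inverting topology
  expect_equal(abs(spec$A0), spec$R2 / (2 * spec$R1))
  # |A| is maximal at f0
  fr <- frequency_response(spec, c(11.9, 11.99, 12, 12.01, 12.1))
  expect_equal(which.max(fr$magnitude), 3L)
})

test_that("unrealizable designs and invalid components are rejected by name", {
  expect_error(design_mfb(12, 0.5, A0_mag = 1), "2\\*Q\\^2 > A0_mag")
  expect_error(design_mfb(-1, 1.5), "f0")
  expect_error(mfb_spec(-1, 1, 1, 1e-7), "strictly positive")
})

test_that("frequency response: 180 degrees and |A0| at f0, band-pass limits", {
  spec <- design_mfb(12, 1.5, A0_mag = 2)
  at_f0 <- frequency_response(spec, 12)
  expect_equal(at_f0$phase_deg, 180)
  expect_equal(at_f0$magnitude, spec$R2 / (2 * spec$R1), tolerance = 1e-12)
  lims <- frequency_response(spec, c(1e-4, 1e6))
  expect_lt(max(lims$magnitude), 1e-3)
})

test_that("component scaling symmetry: R * k, C / k leaves (f0, Q, A0) fixed", {
  spec <- design_mfb(12, 1.5, A0_mag = 1.2, C = 47e-9)
  k <- 7.3
  scaled <- mfb_spec(spec$R1 * k, spec$R2 * k, spec$R3 * k, spec$C / k)
  expect_equal(scaled$f0, spec$f0, tolerance = 1e-12)
  expect_equal(scaled$Q, spec$Q, tolerance = 1e-12)
  expect_equal(scaled$A0, spec$A0, tolerance = 1e-12)
})

test_that("-3 dB bandwidth of the (12 Hz, Q=1.5) design is f0/Q = 8 Hz", {
  spec <- design_mfb(12, 1.5)
  g <- function(f) frequency_response(spec, f)$magnitude - 1 / sqrt(2)
  lo <- stats::uniroot(g, c(4, 12), tol = 1e-10)$root
  hi <- stats::uniroot(g, c(12, 30), tol = 1e-10)$root
  expect_equal(hi - lo, 8, tolerance = 1e-6)
})

test_that("loop phase: delay term, additivity, and polarity", {
  spec <- design_mfb(12, 1.5)
  # pure 42 ms delay contributes 175 degrees at 11.6 Hz
  delay_only <- 360 * 11.6 * 0.042
  expect_equal(round(delay_only), 175)
  no_delay <- loop_config(digital_delay = 0)
  expect_equal(loop_phase(spec, no_delay, 9.3),
               alphaloop:::mfb_phase_deg(spec, 9.3))
  # additivity of delays is exact
  d1 <- loop_config(digital_delay = 0.03)
  d2 <- loop_config(digital_delay = 0.012)
  d12 <- loop_config(digital_delay = 0.042)
  f <- c(8, 11.6, 16)
  expect_equal(loop_phase(spec, d12, f),
               loop_phase(spec, d1, f) + loop_phase(spec, d2, f) -
                 loop_phase(spec, no_delay, f))
  # polarity -1 inserts exactly 180 degrees
  expect_equal(loop_phase(spec, loop_config(polarity = -1), f),
               loop_phase(spec, loop_config(), f) + 180)
})

test_that("filter phase decreases monotonically across the 8-16 Hz passband", {
  spec <- design_mfb(12, 1.5)
  ph <- alphaloop:::mfb_phase_deg(spec, seq(8, 16, by = 0.1))
  expect_true(all(diff(ph) < 0))
})

test_that("discrete realization matches the analytic response over 5-30 Hz", {
  spec <- design_mfb(12, 1.5)
  f <- seq(5, 30, by = 0.25)
  hd <- alphaloop:::mfb_biquad_response(spec, 1000, f)
  ha <- frequency_response(spec, f)
  expect_lt(max(abs(Mod(hd) / ha$magnitude - 1)), 0.01)
  dphi <- ((Arg(hd) * 180 / pi) %% 360 - ha$phase_deg + 180) %% 360 - 180
  expect_lt(max(abs(dphi)), 2)
})

test_that("apply_filter: zero in/zero out, steady-state sinusoid gain and phase", {
  spec <- design_mfb(12, 1.5)
  loop <- loop_config(command_limit = Inf)
  expect_equal(apply_filter(rep(0, 1000), 1000, spec, loop), rep(0, 1000))
  tt <- (0:9999) / 1000
  x <- sin(2 * pi * 12 * tt)
  y <- apply_filter(x, 1000, spec, loop)
  seg <- 5000:9000  # steady state
  expect_equal(stats::sd(y[seg]) / stats::sd(x[seg]), 1, tolerance = 0.02)
  lag <- (-circular_mean_deg(phase_difference_deg(x[seg], y[seg]))) %% 360
  expected <- loop_phase(spec, loop, 12) %% 360
  err <- abs((lag - expected + 180) %% 360 - 180)
  expect_lt(err, 2)
})

test_that("apply_filter clips at the command limit and validates fs", {
  spec <- design_mfb(12, 1.5)
  tt <- (0:4999) / 1000
  y <- apply_filter(5 * sin(2 * pi * 12 * tt), 1000, spec,
                    loop_config(command_limit = 0.5))
  expect_lte(max(abs(y)), 0.5)
  expect_error(apply_filter(rep(0, 100), 50, spec), "too low")
  expect_error(apply_filter(c(1, NA, 2), 1000, spec), "finite")
})

test_that("filter spec survives the flat key-value config round trip", {
  spec <- design_mfb(10.5, 2, A0_mag = 1.4, C = 220e-9)
  back <- filter_spec_from_config(filter_spec_config(spec))
  expect_equal(back$f0, spec$f0, tolerance = 1e-12)
  expect_equal(back$Q, spec$Q, tolerance = 1e-12)
  expect_equal(back$A0, spec$A0, tolerance = 1e-12)
  expect_error(filter_spec_from_config(c(R1 = 1, R2 = 2)), "must name")
})
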