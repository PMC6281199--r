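test_that("median normalization reproduces the hand-computed toy tensor", {
  # 3 epochs x 4 timepoints, one frequency; worked through by hand:
  # epoch medians 3, 2, 3 -> step-1 rows (1/3,2/3,4/3,8/3), (1,1,1,1),
  # (1/3,1,1,3); across-epoch medians (1/3, 1, 1, 8/3); baseline (t <= -1)
  # grand median 2/3; dB = 10*log10(c(1/2, 3/2, 3/2, 4))
  pow <- array(NA_real_, c(3, 1, 1, 4))
  pow[1, 1, 1, ] <- c(1, 2, 4, 8)
  pow[2, 1, 1, ] <- c(2, 2, 2, 2)
  pow[3, 1, 1, ] <- c(1, 3, 3, 9)
  tfr <- make_tfr(pow, freqs = 10, time = c(-2, -1, 0, 1))
  norm <- normalize_median_db(tfr, baseline = c(-2, -1))
  expect_equal(norm$db[1, 1, ], 10 * log10(c(0.5, 1.5, 1.5, 4)))
  expect_equal(norm$step1[1, 1, 1, ], c(1, 2, 4, 8) / 3)
  expect_equal(norm$step1[2, 1, 1, ], rep(1, 4))
  expect_equal(norm$normalization, "normalized_db")
})

test_that("normalization closed forms: constant power and post-offset doubling", {
  pow <- array(5, c(4, 1, 2, 100))
  tfr <- make_tfr(pow, freqs = c(8, 9), time = seq(-5, 4.9, 0.1))
  norm <- normalize_median_db(tfr)
  expect_equal(max(abs(norm$db)), 0)
  pow2 <- pow
  pow2[, , , 51:100] <- 10  # doubled after offset
  norm2 <- normalize_median_db(make_tfr(pow2, c(8, 9), seq(-5, 4.9, 0.1)))
  expect_equal(unique(round(norm2$db[1, 1, 51:100], 10)),
               round(10 * log10(2), 10))
  expect_equal(max(abs(norm2$db[1, 1, 1:50])), 0)
})

test_that("normalization is scale-invariant and rejects degenerate input", {
  withr::with_seed(3, {
    pow <- array(stats::rexp(5 * 1 * 2 * 80), c(5, 1, 2, 80))
  })
  time <- seq(-5, 4.875, length.out = 80)
  n1 <- normalize_median_db(make_tfr(pow, c(8, 9), time))
  nk <- normalize_median_db(make_tfr(pow * 37.5, c(8, 9), time))
  expect_equal(n1$db, nk$db, tolerance = 1e-12)
  expect_error(normalize_median_db(make_tfr(array(0, c(2, 1, 1, 10)), 8,
                                            seq(-5, 4, 1))), "degenerate")
  expect_error(normalize_median_db(n1), "already normalized")
})

test_that("band mean averages the inclusive discrete frequency set", {
  db <- array(NA_real_, c(1, 26, 10))  # dB trace = frequency index
  for (f in 1:26) db[1, f, ] <- f
  norm <- structure(list(db = db, freqs = 5:30,
                         time = seq(-5, 4, length.out = 10)),
                    class = "al_norm")
  alpha <- band_mean(norm, band_def("alpha", 8, 15))
  # inclusive endpoints: mean of the 8 values 4..11 (freqs 8..15)
  expect_equal(alpha$db[1, 1], mean(4:11))
  beta <- band_mean(norm, band_def("beta", 15, 30))
  expect_equal(beta$db[1, 1], mean(11:26))  # 15 Hz belongs to both bands
  expect_error(band_mean(norm, band_def("hgp", 80, 200)), "outside")
})

test_that("window summary: ramp closed form, wider window, constants", {
  time <- seq(0, 1, by = 0.001)
  ramp <- matrix(time, nrow = 1)  # 0 -> 1 dB over (0, 1) s
  ws <- window_summary(ramp, window = c(0.5, 1), time = time)
  expect_equal(ws$mean, 0.75, tolerance = 1e-3)
  const <- matrix(2.5, nrow = 3, ncol = length(time))
  wc <- window_summary(const, window = c(0.5, 1), time = time)
  expect_equal(unname(wc$values), rep(2.5, 3))
  # the wider 0.5-1.5 s window changes the estimate in a controlled way
  time2 <- seq(0, 2, by = 0.001)
  decay <- matrix(pmax(0, 1 - time2), nrow = 1)
  w_narrow <- window_summary(decay, c(0.5, 1), time = time2)
  w_wide <- window_summary(decay, c(0.5, 1.5), time = time2)
  expect_gt(w_narrow$mean, w_wide$mean)
  expect_error(window_summary(ramp, c(0.5, 2), time = time), "outside")
})

test_that("spotlight selection matches exhaustive grid enumeration", {
  brute <- function(map, radius) {
    ctl <- map[map$controller | map$controller_ref, ]
    hits <- integer(0)
    for (i in seq_len(nrow(map))) {
      if (map$array[i] != ctl$array[1]) next
      if (map$controller[i] || map$controller_ref[i]) next
      d <- min(abs(map$row[i] - ctl$row) + abs(map$col[i] - ctl$col))
      if (d <= radius) hits <- c(hits, map$channel[i])
    }
    hits
  }
  m_int <- channel_map()  # interior controller at (5,5)-(5,6)
  expect_equal(sort(spotlight(m_int, 2)), sort(brute(m_int, 2)))
  expect_length(spotlight(m_int, 0), 0)
  m_edge <- channel_map(controller = c(1, 2))  # top edge of the grid
  expect_equal(sort(spotlight(m_edge, 2)), sort(brute(m_edge, 2)))
  expect_lt(length(spotlight(m_edge, 2)), length(spotlight(m_int, 2)))
})

test_that("channel aggregation order (linear vs per-electrode dB) is insensitive", {
  s <- small_session(seed = 31, n_blocks = 10, n_arrays = 1)
  ch <- select_channels(s)
  kept <- reject_trials(s$events, max_duration = 11)
  on <- epoch_events(s, "onset", c(-5, 5), channels = ch, trials = kept)
  off <- epoch_events(s, "offset", c(-5, 5), channels = ch, trials = kept)
  fam <- alphaloop:::condition_family_data(
    on, off, 8:15, 8:15, 4, bands_default()["alpha"],
    c(-5, -1), c(0.5, 1), 4L, per_channel = TRUE)
  tens <- alphaloop:::band_tensor(fam$step1[["1"]], fam$freqs, fam$time,
                                  bands_default()$alpha, c(-5, -1),
                                  c(0.5, 1), 4L)
  linear_first <- alphaloop:::tensor_summary(tens)
  db_first <- mean(fam$per_channel$value)
  expect_lt(abs(linear_first - db_first), 0.2)
})
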