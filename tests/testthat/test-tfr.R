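test_that("tfr configuration invariants", {
  expect_error(tfr_config(freqs = c(10, 9)), "increasing")
  expect_error(tfr_config(freqs = 5:10, n_cycles = 5:9), "index-wise")
  expect_error(tfr_config(freqs = 5:10, n_cycles = rep(2, 6)), ">= 3")
  cfg <- tfr_config()
  expect_equal(cfg$freqs, 5:30)
  expect_equal(cfg$n_cycles, cfg$freqs)  # matched index-wise
})

test_that("morlet wavelets are zero-mean with unit discrete energy", {
  for (f in c(5, 12, 30)) {
    w <- morlet_wavelet(f, f, fs = 1000)
    expect_lt(Mod(sum(w)), 1e-10)
    expect_equal(sum(Mod(w)^2), 1, tolerance = 1e-12)
    expect_equal(length(w) %% 2, 1)
  }
})

test_that("pure sinusoid: power peaks at its frequency, constant over valid times", {
  fs <- 200
  tt <- (0:1999) / fs
  ep <- make_epochs(array(sin(2 * pi * 10 * tt), c(1, 1, 2000)), fs)
  tf <- morlet_power(ep, tfr_config(freqs = 7:13, n_cycles = 7:13,
                                    hf_freqs = NULL))
  prof <- apply(tf$power[1, 1, , ], 1, mean, na.rm = TRUE)
  expect_equal(which.max(prof), which(tf$freqs == 10))
  mid <- tf$power[1, 1, 4, 500:1500]
  expect_lt(stats::sd(mid) / mean(mid), 0.01)
  # leakage: power 3 Hz off-peak is far below 10% of the peak
  expect_lt(prof[1] / prof[4], 0.1)
  expect_lt(prof[7] / prof[4], 0.1)
})

test_that("zero signal gives zero power; scaling voltage by k scales power by k^2", {
  fs <- 200
  z <- morlet_power(make_epochs(array(0, c(1, 1, 1000)), fs),
                    tfr_config(freqs = 10, n_cycles = 10, hf_freqs = NULL))
  expect_equal(max(z$power, na.rm = TRUE), 0)
  x <- stats::rnorm(1000)
  cfg <- tfr_config(freqs = c(8, 12), n_cycles = c(8, 12), hf_freqs = NULL)
  p1 <- morlet_power(make_epochs(array(x, c(1, 1, 1000)), fs), cfg)
  p3 <- morlet_power(make_epochs(array(3 * x, c(1, 1, 1000)), fs), cfg)
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-12)
})

test_that("white-noise power is flat across frequencies (unit-energy convention)", {
  withr::with_seed(42, {
    d <- array(stats::rnorm(200 * 1 * 1500, 0, 2), c(200, 1, 1500))
  })
  tf <- morlet_power(make_epochs(d, 200),
                     tfr_config(freqs = c(6, 10, 18, 30),
                                n_cycles = c(6, 10, 18, 30), hf_freqs = NULL))
  mp <- apply(tf$power, 3, mean, na.rm = TRUE)
  # expected power sigma^2 = 4 at every frequency
  expect_true(all(abs(mp / 4 - 1) < 0.05))
})

test_that("edge samples inside the wavelet half-length are flagged invalid", {
  fs <- 200
  tf <- morlet_power(make_epochs(array(stats::rnorm(600), c(1, 1, 600)), fs),
                     tfr_config(freqs = 8, n_cycles = 8, hf_freqs = NULL))
  w <- morlet_wavelet(8, 8, fs)
  h <- (length(w) - 1) / 2
  expect_true(all(is.na(tf$power[1, 1, 1, 1:h])))
  expect_true(all(is.na(tf$power[1, 1, 1, (600 - h + 1):600])))
  expect_false(anyNA(tf$power[1, 1, 1, (h + 1):(600 - h)]))
  # epoch shorter than the wavelet support errors, naming the frequency
  expect_error(morlet_power(make_epochs(array(0, c(1, 1, 100)), fs),
                            tfr_config(freqs = 5, n_cycles = 30,
                                       hf_freqs = NULL)), "5 Hz")
})

test_that("evoked median: identity, antisymmetry, and incoherent-alpha shrinkage", {
  fs <- 200
  same <- array(rep(sin(2 * pi * 10 * (0:999) / fs), each = 3), c(3, 1, 1000))
  ev <- evoked_median(make_epochs(same, fs))
  expect_equal(ev$data[1, 1, ], same[1, 1, ])
  x <- stats::rnorm(1000)
  anti <- array(0, c(3, 1, 1000))
  anti[1, 1, ] <- x; anti[2, 1, ] <- -x
  expect_equal(evoked_median(make_epochs(anti, fs))$data[1, 1, ],
               rep(0, 1000))
  # random-phase alpha: evoked power is far below single-trial power
  withr::with_seed(7, {
    ph <- stats::runif(100, 0, 2 * pi)
    d <- array(NA_real_, c(100, 1, 1000))
    tt <- (0:999) / fs
    for (i in 1:100) d[i, 1, ] <- sin(2 * pi * 10 * tt + ph[i])
  })
  ev2 <- evoked_median(make_epochs(d, fs))
  expect_lt(mean(ev2$data^2), 0.02 * mean(d^2))
})

test_that("PL/NPL decomposition: identical trials and random phases", {
  fs <- 200
  tt <- (0:999) / fs
  cfg <- tfr_config(freqs = 10, n_cycles = 10, hf_freqs = NULL)
  same <- array(rep(sin(2 * pi * 10 * tt), each = 4), c(4, 1, 1000))
  r <- pl_npl_power(make_epochs(same, fs), cfg)
  tot <- morlet_power(make_epochs(same, fs), cfg)
  expect_lt(max(r$npl$power, na.rm = TRUE), 1e-20)
  expect_equal(r$pl$power[1, 1, 1, ], tot$power[1, 1, 1, ], tolerance = 1e-10)
  expect_equal(r$pl$stream, "PL")
  expect_equal(r$npl$stream, "NPL")
  # uniformly random phases: PL -> 0 relative to total as n grows
  withr::with_seed(8, {
    d <- array(NA_real_, c(200, 1, 1000))
    for (i in 1:200) {
      d[i, 1, ] <- sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(1000, 0, 0.3)
    }
  })
  r2 <- pl_npl_power(make_epochs(d, fs), cfg)
  tot2 <- morlet_power(make_epochs(d, fs), cfg)
  expect_lt(mean(r2$pl$power, na.rm = TRUE),
            0.05 * mean(tot2$power, na.rm = TRUE))
  # stim-locked component is captured by PL at its frequency
  locked <- array(NA_real_, c(20, 1, 1000))
  withr::with_seed(9, {
    for (i in 1:20) {
      locked[i, 1, ] <- sin(2 * pi * 10 * tt) + stats::rnorm(1000, 0, 1)
    }
  })
  cfg2 <- tfr_config(freqs = c(7, 10, 13), n_cycles = c(7, 10, 13),
                     hf_freqs = NULL)
  r3 <- pl_npl_power(make_epochs(locked, fs), cfg2)
  prof <- apply(r3$pl$power[1, 1, , ], 1, mean, na.rm = TRUE)
  expect_equal(which.max(prof), 2L)
})

test_that("power-domain pre/post concatenation keeps trials aligned and NA edges", {
  s <- small_session(seed = 13, n_blocks = 1, fs = 250)
  ch <- select_channels(s)[1:2]
  on <- epoch_events(s, "onset", c(-5, 5), channels = ch)
  off <- epoch_events(s, "offset", c(-5, 5), channels = ch)
  cfg <- tfr_config(freqs = c(8, 12), n_cycles = c(8, 12), hf_freqs = NULL)
  tf_on <- morlet_power(on, cfg)
  tf_off <- morlet_power(off, cfg)
  cat_tf <- concat_prepost_power(tf_on, tf_off)
  n_half <- sum(tf_on$time < 0)
  expect_equal(dim(cat_tf$power)[4], 2 * n_half)
  # outer edges invalid, splice interior fully valid
  sl <- cat_tf$power[1, 1, 1, ]
  expect_true(anyNA(sl[1:10]))
  expect_false(anyNA(sl[(n_half - 10):(n_half + 10)]))
  expect_true(anyNA(sl[(2 * n_half - 5):(2 * n_half)]))
  # post half is the offset-aligned power, matched by trial id
  expect_equal(cat_tf$power[, , , n_half + 1:n_half],
               tf_off$power[, , , which(tf_off$time >= 0)])
})
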