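test_that("bootstrap vs zero: degenerate input, symmetry, seed reproducibility", {
  cfg <- stats_config(n_boot = 400, seed = 5)
  expect_warning(st <- bootstrap_vs_zero(rep(2, 5), cfg), "degenerate")
  expect_equal(st$ci, c(2, 2))
  expect_equal(st$p_below, 0)
  sym <- bootstrap_vs_zero(c(-3, -1, 1, 3), stats_config(n_boot = 2000, seed = 1))
  expect_gt(sym$p_above, 0.3); expect_lt(sym$p_above, 0.7)
  a <- bootstrap_vs_zero(c(0.1, 0.4, -0.2, 0.3), cfg)
  b <- bootstrap_vs_zero(c(0.1, 0.4, -0.2, 0.3), cfg)
  expect_identical(tidy(a), tidy(b))
  expect_error(bootstrap_vs_zero(1), ">= 2")
})

test_that("bootstrap matches the exhaustive n=5 enumeration oracle", {
  vals <- c(-1, 2, 3, 4, 5)
  # oracle: all 5^5 resamples with replacement, exact mass above zero
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  means <- rowMeans(matrix(vals[grid], nrow = nrow(grid)))
  exact_above <- mean(means > 0)
  exact_mean <- mean(means)
  st <- bootstrap_vs_zero(vals, stats_config(n_boot = 20000, seed = 2))
  expect_equal(st$p_above, exact_above, tolerance = 0.01)
  expect_equal(mean(st$dist), exact_mean, tolerance = 0.05)
})

test_that("condition permutation: exhaustive oracle on 3+3 and trivial cases", {
  st <- perm_condition(c(1, 2, 3), c(10, 11, 12), stats_config(n_perm = 500))
  expect_true(st$exhaustive)
  expect_equal(st$n_draws, choose(6, 3))
  expect_equal(st$observed, -9)
  expect_equal(st$p, 2 / 20)  # only the observed split and its mirror reach |9|
  # brute-force oracle recomputed independently
  pool <- c(1, 2, 3, 10, 11, 12)
  combs <- utils::combn(6, 3)
  null <- apply(combs, 2, function(ix) mean(pool[ix]) - mean(pool[-ix]))
  expect_equal(sort(st$dist), sort(null))
  same <- perm_condition(c(1, 2, 3, 4), c(1, 2, 3, 4),
                         stats_config(n_perm = 500))
  expect_gt(same$p, 0.9)
  expect_error(perm_condition(1, c(1, 2)), ">= 2")
})

test_that("permutation p moves monotonically as one group shifts", {
  base <- c(0.3, -0.1, 0.2, 0.05, -0.2, 0.15)
  other <- c(0.1, -0.3, 0.0, 0.2, -0.1, 0.05)
  cfg <- stats_config(n_perm = 2000, seed = 3)
  ps <- vapply(c(0, 0.5, 1, 2),
               function(d) perm_condition(base + d, other, cfg)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("subsampled permutations equalize group sizes per draw", {
  withr::with_seed(4, {
    a <- stats::rnorm(30); b <- stats::rnorm(10)
  })
  cfg <- stats_config(n_perm = 300, subsample_to = 10, seed = 6)
  st <- perm_condition(a, b, cfg)
  expect_false(st$exhaustive)
  expect_equal(st$n_draws, 300)
  expect_equal(st$observed, mean(a) - mean(b))  # observed uses full groups
  expect_true(st$p >= 0 && st$p <= 1)
})

test_that("array permutation: exhaustive 3+3 oracle and effect detection", {
  vals <- c(0.5, 0.6, 0.7, 0.1, 0.0, 0.2)
  arrays <- rep(1:2, each = 3)
  st <- perm_array(vals, arrays, stats_config(n_perm = 100))
  expect_true(st$exhaustive)
  combs <- utils::combn(6, 3)
  null <- apply(combs, 2, function(ix) mean(vals[ix]) - mean(vals[-ix]))
  expect_equal(sort(st$dist), sort(null))
  expect_equal(st$p, mean(abs(null) >= abs(st$observed)))
  expect_error(perm_array(vals, rep(1, 6)), "two arrays")
  # per-electrode effect on one array only is detected at n = 96 + 96
  withr::with_seed(7, {
    v <- c(stats::rnorm(96, 0.1, 0.05), stats::rnorm(96, 0, 0.05))
  })
  st2 <- perm_array(v, rep(1:2, each = 96), stats_config(n_perm = 500, seed = 8))
  expect_lt(st2$p, 0.05)
})

test_that("BH-FDR matches the direct step-up formula within families", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.2), 0.2)
  # family-of-3 consistency: p = 0.006 maps to 0.018 within its family
  fam <- fdr_bh(c(0.006, 0.5, 0.9, 0.001, 0.2, 0.8),
                family = rep(c("alpha", "beta"), each = 3))
  expect_equal(fam[1], 0.018)
  expect_equal(fam[4], 0.003)
  # agrees with p.adjust applied per family
  expect_equal(fam[1:3], stats::p.adjust(c(0.006, 0.5, 0.9), "BH"))
  p <- c(0.04, 0.01, 0.9, 0.2)
  expect_true(all(fdr_bh(p) >= p))
})

test_that("stat results tidy into one-row tibbles with p_fdr-ready fields", {
  st <- perm_condition(c(1, 2, 3), c(2, 3, 4), stats_config(n_perm = 100))
  td <- tidy(st)
  expect_equal(nrow(td), 1)
  expect_true(all(c("estimate", "p.value", "n.draws", "seed") %in% names(td)))
  expect_identical(glance(st)$estimate, td$estimate)
})

test_that("band-tensor statistics recompute normalization within draws", {
  # two-trial-group tensor with a known mean offset in the window columns
  withr::with_seed(9, {
    s <- small_session(seed = 17, n_blocks = 2, n_arrays = 1)
  })
  ch <- select_channels(s)
  kept <- reject_trials(s$events, max_duration = 11)
  on <- epoch_events(s, "onset", c(-5, 5), channels = ch, trials = kept)
  off <- epoch_events(s, "offset", c(-5, 5), channels = ch, trials = kept)
  fam <- alphaloop:::condition_family_data(
    on, off, 8:15, 8:15, 4, bands_default()["alpha"],
    c(-5, -1), c(0.5, 1), 4L, per_channel = FALSE)
  tens <- alphaloop:::band_tensor(fam$step1[["1"]], fam$freqs, fam$time,
                                  bands_default()$alpha, c(-5, -1),
                                  c(0.5, 1), 4L)
  st <- bootstrap_vs_zero(tens, stats_config(n_boot = 200, seed = 10))
  expect_equal(st$n, 20)
  expect_true(st$ci[1] <= st$observed && st$observed <= st$ci[2])
  # identity draw reproduces the observed estimate
  expect_equal(alphaloop:::tensor_summary(tens), st$observed)
  # trial-level scalar path agrees in sign/scale with the tensor estimate
  tv <- alphaloop:::tensor_trial_values(tens)
  expect_equal(length(tv), 20)
  expect_lt(abs(mean(tv) - st$observed), 0.5)
})
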