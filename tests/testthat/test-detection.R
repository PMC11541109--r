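test_that("neo matches its definition exactly on integer series", {
  # hand evaluation: x = (1, 2, 3) -> psi = 4 - 3 = 1
  expect_equal(neo(c(1, 2, 3)), 1)
  # constant and linear-ramp identities
  expect_equal(neo(rep(7, 10)), rep(0, 8))
  expect_equal(neo(3 * (1:20) + 5), rep(9, 18))
  expect_length(neo(c(1, 2)), 0)
  # oracle: naive three-term loop on random integers
  set.seed(1)
  x <- sample(-256:255, 200, TRUE)
  oracle <- vapply(2:199, function(n) x[n]^2 - x[n - 1] * x[n + 1], numeric(1))
  expect_equal(neo(x), oracle)
})

test_that("zero-crossing counter and log rate follow the sign-bit rule", {
  expect_equal(zero_crossing_log_rate(c(1, 2, 3, 0.5))$zc_count, 0L)
  alt <- rep(c(1, -1), length.out = 9)
  z <- zero_crossing_log_rate(alt)
  expect_equal(z$zc_count, 8L)
  expect_equal(z$log_rate, 3L)           # floor(log2(9)) = 3
  expect_equal(zero_crossing_log_rate(5)$zc_count, 0L)
  # zero counts as positive
  expect_equal(zero_crossing_log_rate(c(0, -1, 0, -1))$zc_count, 3L)
})

test_that("noise estimator is a smoothed fixed point with geometric decay", {
  expect_equal(noise_estimate(rep(0, 64)), 0)
  # constant |psi| = c converges to c from any state
  nl <- 0
  for (i in 1:60) nl <- noise_estimate(rep(10, 64), state = nl)
  expect_equal(nl, 10, tolerance = 1e-6)
  # an isolated impulse is attenuated below a quarter after one window
  imp <- c(1000, rep(0, 63))
  expect_lt(noise_estimate(imp, state = 0), 1000 / 4)
})

test_that("threshold combines noise and rate monotonically", {
  expect_equal(compute_threshold(0), 1)               # floor
  expect_equal(compute_threshold(10, log_rate = 0, k = 8), 80)
  expect_equal(compute_threshold(20, log_rate = 0, k = 8),
               2 * compute_threshold(10, log_rate = 0, k = 8))
  # nondecreasing in both arguments
  nl <- seq(0, 50, by = 5)
  th <- vapply(nl, compute_threshold, numeric(1), log_rate = 2)
  expect_true(all(diff(th) >= 0))
  lr <- 0:6
  th2 <- vapply(lr, function(l) compute_threshold(10, l), numeric(1))
  expect_true(all(diff(th2) >= 0))
  expect_error(compute_threshold(-1), "non-negative")
})

test_that("an all-zero recording yields no detections", {
  rec <- new_recording(matrix(0L, 1, 2000))
  ev <- detect_spikes(rec, 1)
  expect_equal(nrow(ev$events), 0)
})

test_that("an isolated spike is detected once with accurate onset", {
  tpl <- default_spike_templates(1)
  cfg <- generator_config(duration_s = 0.5, firing_rate_hz = 4, noise_sd = 1,
                          seed = 31)
  g <- generate_recording(cfg, templates = tpl)
  # keep only well-isolated truth spikes for the +/-2 sample check
  ev <- detect_spikes(g$recording, 1)
  iso <- g$ground_truth$onset[c(TRUE, diff(g$ground_truth$onset) > 200)]
  for (o in iso) {
    d <- min(abs(ev$events$onset - o))
    expect_lte(d, 2)
  }
  expect_error(detect_spikes(g$recording, 99), "unknown channel")
})

test_that("detection recall on the 60 spikes/s regime is at least 0.95", {
  g <- fixture_recording(duration_s = 5, seed = 7)
  ev <- detect_spikes(g$recording, 1)
  r <- detection_recall(ev, g$ground_truth)
  expect_gte(r$recall, 0.95)
})

test_that("refractory lockout and window partition invariants hold", {
  g <- fixture_recording(duration_s = 3, seed = 9)
  ev <- detect_spikes(g$recording, 1)
  expect_true(all(diff(ev$events$detect_index) >= 64))
  expect_true(all(diff(ev$events$onset) >= 64))
  x <- g$recording$samples[1, ]
  for (i in seq_len(min(10, nrow(ev$events)))) {
    o <- ev$events$onset[i]
    expect_identical(ev$waveforms[i, ], x[o:(o + 63)])
    expect_true(o <= ev$events$detect_index[i] &&
                  ev$events$detect_index[i] < o + 64)
  }
})
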