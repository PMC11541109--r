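test_that("silent configurations produce all-zero recordings with empty truth", {
  cfg <- generator_config(duration_s = 0.1, firing_rate_hz = 0, noise_sd = 0,
                          lfp_amplitude = 0, seed = 1)
  g <- generate_recording(cfg, templates = list())
  expect_true(all(g$recording$samples == 0L))
  expect_equal(nrow(g$ground_truth), 0)
})

test_that("generation is deterministic in the seed and config", {
  cfg <- generator_config(n_channels = 2, duration_s = 0.3, seed = 42)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_recording(generator_config(n_channels = 2, duration_s = 0.3,
                                            seed = 43))
  expect_false(identical(g1$recording$samples, g3$recording$samples))
})

test_that("ground-truth spike counts follow Poisson statistics", {
  # aggregate 60 spikes/s for 60 s: expect 3600 +/- 3 sd
  cfg <- generator_config(duration_s = 60, noise_sd = 0, seed = 5)
  g <- generate_recording(cfg)
  expect_lt(abs(nrow(g$ground_truth) - 3600), 3 * sqrt(3600))
})

test_that("every emitted sample respects the signed bit-depth range", {
  for (seed in 1:5) {
    cfg <- generator_config(duration_s = 0.2, noise_sd = 30,
                            lfp_amplitude = 60, lfp_spatial_mixing = 0.5,
                            n_channels = 3, seed = seed)
    g <- generate_recording(cfg)
    expect_true(all(g$recording$samples >= -256L &
                      g$recording$samples <= 255L))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(firing_rate_hz = -1), "non-negative")
  expect_error(generator_config(noise_sd = -1), "non-negative")
  expect_error(generator_config(bit_depth = 1), "bit depth")
  expect_error(generate_recording(generator_config(firing_rate_hz = 10),
                                  templates = list()), "templates")
})

test_that("recording files round-trip bit-exactly through the raw+sidecar format", {
  g <- fixture_recording(duration_s = 0.2)
  path <- tempfile(fileext = ".bin")
  write_recording(g$recording, path)
  back <- read_recording(path)
  expect_identical(back$samples, g$recording$samples)
  expect_equal(back$fs, g$recording$fs)
  expect_equal(back$bit_depth, g$recording$bit_depth)

  # empty recording round-trips to empty
  empty <- new_recording(matrix(integer(0), nrow = 2, ncol = 0))
  p2 <- tempfile(fileext = ".bin")
  write_recording(empty, p2)
  back2 <- read_recording(p2)
  expect_equal(dim(back2$samples), c(2L, 0L))
})

test_that("corrupt recording files raise format errors", {
  g <- fixture_recording(duration_s = 0.1, n_channels = 3)
  path <- tempfile(fileext = ".bin")
  write_recording(g$recording, path)
  # truncate so the payload is no longer divisible by the channel count
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  writeBin(raw[1:(sz - 2)], path)
  expect_error(read_recording(path), "divisible")
  file.remove(paste0(path, ".json"))
  expect_error(read_recording(path), "sidecar")
})

test_that("lfp pair generator honours its degenerate contracts", {
  p0 <- generate_lfp_pair(200, gamma_true = 0, noise_sd = 0, seed = 2)
  expect_true(all(p0$child == 0L))
  p1 <- generate_lfp_pair(200, gamma_true = 1, noise_sd = 0, seed = 2)
  expect_identical(p1$child, p1$parent)
  expect_error(generate_lfp_pair(50, 0.5), "at least 100")
})

test_that("empirical firing rate converges to the configured rate", {
  cfg <- generator_config(duration_s = 30, firing_rate_hz = c(10, 0, 0),
                          noise_sd = 0, seed = 8)
  g <- generate_recording(cfg)
  expect_lt(abs(nrow(g$ground_truth) - 300), 3 * sqrt(300))
})
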