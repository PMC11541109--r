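test_that("temporal decorrelation is first-difference and invertible", {
  expect_true(all(temporal_decorrelate(rep(9L, 10))[-1] == 0L))
  expect_true(all(temporal_decorrelate(seq(0L, 90L, 10L))[-1] == 10L))
  set.seed(1)
  x <- sample(-256:255, 300, TRUE)
  expect_identical(temporal_recorrelate(temporal_decorrelate(x)), x)
})

test_that("gamma closed form equals the energy-minimizing oracle", {
  expect_equal(estimate_gamma(c(1, -2, 3), c(1, -2, 3)), 1)
  expect_equal(estimate_gamma(c(1, -1, 1, -1), c(1, 1, 1, 1)), 0)
  expect_warning(g0 <- estimate_gamma(1:4, rep(0, 4)), "zero-energy")
  expect_equal(g0, 0)
  set.seed(10)
  grid <- seq(-4, 4, by = 1e-4)
  for (i in 1:20) {
    ec <- rnorm(150); er <- rnorm(150)
    g_hat <- estimate_gamma(ec, er)
    en <- vapply(grid, function(g) sum((ec - g * er)^2), numeric(1))
    g_grid <- grid[which.min(en)]
    expect_lt(abs(g_hat - g_grid), 1e-3)
    # optimality of the closed form
    expect_lte(sum((ec - g_hat * er)^2), min(en) + 1e-9)
  }
})

test_that("energy is the sum of squares", {
  expect_equal(energy(numeric(0)), 0)
  expect_equal(energy(3), 9)
  expect_equal(energy(c(-2, 2)), 8)
})

test_that("a planted gamma is recovered from quantized series", {
  p <- generate_lfp_pair(4000, 0.7, seed = 5, noise_sd = 2)
  g_hat <- estimate_gamma(temporal_decorrelate(p$child),
                          temporal_decorrelate(p$parent), 1, 2000)
  expect_lt(abs(g_hat - 0.7), 0.05)
})

test_that("channel-tree training yields valid, deterministic spanning trees", {
  g <- fixture_lfp_group(n_channels = 2, seed = 12)
  t2 <- train_channel_tree(g$recording)
  expect_equal(t2$root, 1)
  expect_equal(length(t2$parent), 1)

  # 3 channels: ch2 = scaled ch1, ch3 independent
  set.seed(4)
  base <- round(50 * as.vector(neurocodec:::lfp_noise(1, 2000, 20000)))
  other <- round(50 * as.vector(neurocodec:::lfp_noise(1, 2000, 20000)))
  rec <- new_recording(rbind(base, round(0.8 * base), other), bit_depth = 9)
  tr <- train_channel_tree(rec, n0 = 1, N = 1500)
  expect_equal(unname(tr$parent["2"]), 1)

  g6 <- fixture_lfp_group(n_channels = 6, seed = 13)
  tr6 <- train_channel_tree(g6$recording)
  expect_equal(length(tr6$parent), 5)            # n - 1 edges
  expect_setequal(tr6$order, 1:6)                # all reachable
  # acyclic: walking parents always terminates at the root
  for (ch in names(tr6$parent)) {
    seen <- integer(0); cur <- as.integer(ch)
    while (cur != tr6$root) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- tr6$parent[as.character(cur)]
    }
  }
  expect_identical(train_channel_tree(g6$recording),
                   train_channel_tree(g6$recording))
  expect_error(train_channel_tree(g6$recording, channels = 1), "at least 2")
})

test_that("cross-channel compression is lossless and exploits correlation", {
  g <- fixture_lfp_group(n_channels = 4, mixing = 0.9, seed = 11)
  tree <- train_channel_tree(g$recording)
  bs <- cce_compress(g$recording, tree)
  out <- cce_decompress(bs)
  expect_identical(out$samples, g$recording$samples)

  # identical parent/child: child codes to almost nothing
  x <- g$recording$samples[1, , drop = FALSE]
  twin <- new_recording(rbind(x, x), bit_depth = 9)
  ttree <- train_channel_tree(twin, n0 = 1, N = min(2000, ncol(x)))
  tbs <- cce_compress(twin, ttree)
  child_bits <- length(tbs$bits[[2]])
  # all residuals are zero: the Rice floor is one bit per sample
  expect_lt(child_bits, 1.2 * ncol(twin$samples))
  expect_identical(cce_decompress(tbs)$samples, twin$samples)

  # spatial decorrelation beats temporal-only coding on correlated groups
  temporal_only_bits <- sum(vapply(1:4, function(ch) {
    length(neurocodec:::rice_adaptive_encode(
      map_to_nonneg(temporal_decorrelate(g$recording$samples[ch, ]))))
  }, numeric(1)))
  expect_lt(bs$payload_nbits, temporal_only_bits)
})

test_that("compression benefit is monotone in the spatial mixing", {
  ssr_at <- function(m) {
    g <- fixture_lfp_group(n_channels = 4, mixing = m, seed = 14)
    tree <- train_channel_tree(g$recording)
    bs <- cce_compress(g$recording, tree)
    ssr(prod(dim(g$recording$samples)) * 9, bs$payload_nbits)
  }
  s <- vapply(c(0.1, 0.5, 0.9), ssr_at, numeric(1))
  expect_true(all(diff(s) > 0))
})
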