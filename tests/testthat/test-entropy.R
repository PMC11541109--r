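test_that("zigzag mapping interleaves signs and is bijective", {
  expect_equal(map_to_nonneg(0L), 0L)
  expect_equal(map_to_nonneg(-1L), 1L)
  expect_equal(map_to_nonneg(1L), 2L)
  expect_equal(map_to_nonneg(c(-2L, 2L)), c(3L, 4L))
  v <- -1024:1024
  expect_identical(map_from_nonneg(map_to_nonneg(v)), v)
})

test_that("rice coding matches the stated bit layout and inverts exactly", {
  expect_identical(golomb_encode(0L, 0L), 0L)              # "0", one bit
  expect_identical(golomb_encode(9L, 2L), c(1L, 1L, 0L, 0L, 1L))  # 110 + 01
  set.seed(3)
  for (k in c(0L, 2L, 5L)) {
    v <- as.integer(rpois(500, 2^k * 1.4))
    dec <- golomb_decode(golomb_encode(v, k), k, length(v))
    expect_identical(dec$values, v)
  }
  expect_error(golomb_decode(c(1L, 1L), 0L, 1L), "truncated")
  expect_error(golomb_encode(-1L, 2L), "non-negative")
})

test_that("rice parameter adaptation tracks the zero fraction", {
  expect_equal(adapt_rice_parameter(1), 0L)
  expect_equal(adapt_rice_parameter(0), 7L)
  expect_true(all(diff(adapt_rice_parameter(seq(0, 1, by = 0.01))) <= 0))
  # geometric source, mean 6: chosen k within 1 of the bit-optimal k
  set.seed(4)
  v <- rgeom(4000, 1 / 7)
  zf <- mean(v == 0)
  lens <- vapply(0:7, function(k) length(golomb_encode(v, k)), numeric(1))
  k_opt <- which.min(lens) - 1L
  expect_lte(abs(adapt_rice_parameter(zf) - k_opt), 1L)
})

test_that("rice coding at the brute-force-optimal k is near the source entropy", {
  set.seed(6)
  for (mu in c(2, 6, 20)) {
    v <- rgeom(6000, 1 / (mu + 1))
    lens <- vapply(0:9, function(k) length(golomb_encode(v, k)), numeric(1))
    p <- 1 / (mu + 1)
    h_source <- (-p * log2(p) - (1 - p) * log2(1 - p)) / p
    expect_lte(min(lens) / length(v), 1.2 * h_source)
  }
})

test_that("block-adaptive rice coding round-trips with mirrored adaptation", {
  set.seed(9)
  v <- as.integer(c(rpois(600, 0.2), rpois(600, 30), rpois(600, 3)))
  bits <- neurocodec:::rice_adaptive_encode(v)
  dec <- neurocodec:::rice_adaptive_decode(bits, length(v))
  expect_identical(dec$values, v)
})

test_that("symbol tables are deterministic, floored and fit the 2 KiB budget", {
  t1 <- train_symbol_table(rep(5L, 3000))
  expect_equal(which.max(t1$counts), 6)           # symbol 5 dominates
  expect_true(all(t1$counts >= 1))
  expect_lte(t1$total, 2^16)
  expect_equal(length(serialize_symbol_table(t1)), 2048)
  set.seed(2)
  v <- sample(0:300, 5000, TRUE)
  expect_identical(train_symbol_table(v), train_symbol_table(v))
  # serialization round-trip preserves the model
  t2 <- deserialize_symbol_table(serialize_symbol_table(t1))
  expect_equal(t2$counts, t1$counts)
  expect_error(train_symbol_table(integer(0)), "empty")
})

test_that("arithmetic coding inverts exactly, including escape literals", {
  set.seed(12)
  v <- as.integer(c(sample(0:50, 3000, TRUE), sample(1500:2500, 50, TRUE)))
  tb <- train_symbol_table(v)
  bits <- ac_encode(v, tb)
  expect_identical(ac_decode(bits, tb, length(v)), v)
})

test_that("arithmetic code length stays within the entropy window", {
  set.seed(13)
  # stationary geometric-like source
  v <- as.integer(rpois(6000, 4))
  tb <- train_symbol_table(v)
  n <- length(v)
  H <- empirical_entropy(v)
  len <- length(ac_encode(v, tb))
  expect_gte(len, n * H - 1)
  expect_lte(len, n * H + 0.1 * n + 128)
  # near-degenerate source: tiny output
  u <- rep(3L, 1000)
  tbl <- train_symbol_table(u)
  expect_lte(length(ac_encode(u, tbl)), 1000 * 0.02 + 64)
})
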