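test_that("maximum-slope alignment is a fixed point with defined tie-breaks", {
  tpl <- as.numeric(default_spike_templates(1)[[1]]$waveform)
  a1 <- align_max_slope(tpl)
  expect_identical(align_max_slope(a1), a1)       # already centered
  # shifted copies align identically where they overlap
  sh <- function(w, s) { o <- numeric(64); src <- seq_len(64) - s
    ok <- src >= 1 & src <= 64; o[ok] <- w[src[ok]]; o }
  for (s in c(-5, -2, 3, 5)) {
    as_ <- align_max_slope(sh(tpl, s))
    ov <- as_ != 0 & a1 != 0
    expect_equal(as_[ov], a1[ov])
  }
  # constant waveform: which.max tie-break gives a defined output
  expect_length(align_max_slope(rep(1, 64)), 64)
  expect_error(align_max_slope(rep(1, 32)), "64 samples")
})

test_that("pca features are orthonormal with a deterministic sign rule", {
  set.seed(3)
  base <- as.numeric(default_spike_templates(1)[[1]]$waveform)
  S <- t(vapply(rnorm(80, sd = 3), function(a) base * (1 + a / 10),
                numeric(64)))
  Fm <- pca_train(S, 2)
  P <- Fm$projection
  expect_equal(unname(P %*% t(P)), diag(2), tolerance = 1e-6)
  # rank-1 data: first component explains essentially all variance
  feats <- mac_project(S, Fm)
  expect_gt(var(feats[, 1]) / (var(feats[, 1]) + var(feats[, 2])), 0.999)
  expect_error(pca_train(S, 11), "at most 10")
})

test_that("discriminative-sample selection finds the separating sample", {
  set.seed(4)
  S <- matrix(rnorm(200 * 64, sd = 0.1), 200, 64)
  lab <- rep(1:2, each = 100)
  S[lab == 2, 40] <- S[lab == 2, 40] + 10     # classes differ at sample 40
  Fm <- af_train(S, lab, 3)
  expect_equal(Fm$positions[1], 40)
  # sparse projection equals direct indexing
  feats <- mac_project(S, Fm)
  expect_equal(feats, S[, Fm$positions], ignore_attr = TRUE)
  expect_error(af_train(S, lab, 8), "at most 7")
})

test_that("blocked projection equals the naive matrix product", {
  set.seed(5)
  S <- matrix(rnorm(50 * 64), 50, 64)
  Fm <- pca_train(S, 4)
  naive <- sweep(S, 2, Fm$center) %*% t(Fm$projection)
  for (b in c(1L, 7L, 16L, 64L))
    expect_equal(mac_project(S, Fm, block = b), naive)
  expect_equal(mac_project(matrix(0, 3, 64), Fm),
               matrix(rep(-Fm$center %*% t(Fm$projection), 3), 3,
                      byrow = TRUE), ignore_attr = TRUE)
})

test_that("k-means recovers well-separated masses and honours the cap", {
  set.seed(9)
  X <- rbind(matrix(rnorm(200, 0, 1e-4), ncol = 2),
             matrix(rnorm(200, 5, 1e-4), ncol = 2),
             cbind(rnorm(100, 0, 1e-4), rnorm(100, 8, 1e-4)))
  mod <- kmeans_train(X, seed = 2)
  expect_equal(mod$k, 3)
  centers <- mod$means[order(mod$means[, 1], mod$means[, 2]), ]
  expect_equal(centers, rbind(c(0, 0), c(0, 8), c(5, 5)), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_identical(kmeans_train(X, seed = 2)$means, mod$means)
  # ten masses: the model caps at 8 clusters
  X10 <- matrix(rep(1:10, each = 30) * 10 + rnorm(300, 0, 1e-3), ncol = 1)
  expect_equal(kmeans_train(X10, seed = 2)$k, 8)
  expect_error(kmeans_train(X10, k_max = 9), "capped")
  expect_error(kmeans_train(X[1:2, ], k = 5), "fewer spikes")
})

test_that("classification follows minimum distance with id tie-breaks", {
  model <- structure(list(means = rbind(c(0, 0), c(4, 0)),
                          covariances = list(diag(2), diag(2)), k = 2L),
                     class = "cluster_model")
  expect_equal(classify(c(0, 0), model), 1L)
  expect_equal(classify(c(4, 0), model), 2L)
  expect_equal(classify(c(2, 0), model), 1L)      # equidistant -> lower id
  # identity covariances: Mahalanobis ranking equals Euclidean
  set.seed(6)
  X <- matrix(rnorm(60), ncol = 2)
  expect_identical(classify(X, model, "euclidean"),
                   classify(X, model, "mahalanobis"))
})

test_that("sorting accuracy uses optimal cluster-class matching", {
  expect_equal(sorting_accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2)), 100)
  expect_equal(sorting_accuracy(rep(1, 5), rep(3, 5)), 100)
  set.seed(7)
  pred <- sample(1:2, 4000, TRUE)
  truth <- rep(1:2, each = 2000)
  expect_equal(sorting_accuracy(pred, truth), 50, tolerance = 0.05)
})

test_that("mahalanobis beats euclidean on anisotropic correlated clusters", {
  fx <- fixture_anisotropic()
  acc <- function(met) 100 * mean(classify(fx$X, fx$model, met) == fx$truth)
  expect_gt(acc("mahalanobis"), acc("euclidean"))
  expect_gt(acc("mahalanobis") - acc("euclidean"), 5)
})

test_that("the full pipeline separates three units at high SNR", {
  g <- fixture_recording(duration_s = 15, firing_rate_hz = 5, seed = 21)
  st <- sort_spikes(g$recording, 1, n_features = 3, kind = "pca", k = 3,
                    seed = 4)
  expect_gte(sorted_accuracy(st, g$ground_truth), 95)
  # AF route runs end to end with its feature cap honoured
  sa <- sort_spikes(g$recording, 1, n_features = 5, kind = "af", k = 3,
                    seed = 4)
  expect_equal(nrow(sa$feature_matrix$projection), 5)
  expect_gte(sorted_accuracy(sa, g$ground_truth), 85)
})
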