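# Shared fixtures: everything is generated in code at test time.

# short default-regime recording (aggregate 60 spikes/s, 9-bit, 20 kHz)
fixture_recording <- function(duration_s = 2, seed = 7, ...) {
  generate_recording(generator_config(duration_s = duration_s, seed = seed,
                                      ...))
}

# multichannel LFP-only group with controllable spatial mixing
fixture_lfp_group <- function(n_channels = 4, mixing = 0.9, seed = 11,
                              duration_s = 0.5, lfp_amplitude = 40,
                              noise_sd = 1) {
  generate_recording(
    generator_config(n_channels = n_channels, duration_s = duration_s,
                     firing_rate_hz = 0, noise_sd = noise_sd,
                     lfp_amplitude = lfp_amplitude,
                     lfp_spatial_mixing = mixing, seed = seed),
    templates = list())
}

# empirical entropy (bits/symbol) of a discrete sample
empirical_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log2(p))
}

# elongated two-cluster feature fixture with correlated noise; the offset has
# a large component along the high-variance axis so Euclidean assignment
# suffers while Mahalanobis does not
fixture_anisotropic <- function(n = 400, seed = 5) {
  set.seed(seed)
  R <- matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2)
  S <- R %*% diag(c(25, 0.2)) %*% t(R)
  L <- chol(S)
  mu2 <- 4 * R[, 1] + 1.2 * R[, 2]
  X1 <- matrix(rnorm(2 * n), ncol = 2) %*% L
  X2 <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% L, 2, mu2, "+")
  Sr <- S + diag(1e-3 * sum(diag(S)) / 2, 2)
  model <- structure(list(means = rbind(c(0, 0), mu2),
                          covariances = list(Sr, Sr), k = 2L),
                     class = "cluster_model")
  list(X = rbind(X1, X2), truth = rep(1:2, each = n), model = model)
}

# score a sorted run against generator ground truth
sorted_accuracy <- function(st, truth) {
  m <- neurocodec:::match_events_to_truth(st$events, truth)
  ok <- !is.na(m)
  sorting_accuracy(st$labels[ok], truth$template_id[m[ok]])
}
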