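#' Nonlinear energy operator
#'
#' `psi[n] = x[n]^2 - x[n-1] * x[n+1]`, computed in exact integer arithmetic
#' and defined only where both neighbours exist (indices `2..n-1` of the
#' input).  The operator amplifies transients, which makes spikes stand out
#' from background noise before thresholding.
#'
#' @param x integer sample series.
#' @return numeric vector of length `length(x) - 2` (empty if shorter than 3),
#'   aligned to input indices `2..n-1`.
#' @export
neo <- function(x) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  x <- as.numeric(x)
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

#' Zero-crossing count and log firing-rate proxy
#'
#' Counts adjacent sample pairs whose sign bits differ (zero counts as
#' positive, matching a two's-complement sign-bit test) and compresses the
#' count logarithmically: `log_rate = floor(log2(zc_count + 1))`.
#'
#' @param psi_window a window of NEO output samples.
#' @return list with `zc_count` and `log_rate`.
#' @export
zero_crossing_log_rate <- function(psi_window) {
  if (length(psi_window) == 0) stopf("empty window")
  neg <- psi_window < 0
  zc <- if (length(neg) > 1) sum(neg[-1] != neg[-length(neg)]) else 0L
  list(zc_count = as.integer(zc), log_rate = as.integer(floor(log2(zc + 1))))
}

#' Noise-level estimate from rectified NEO output
#'
#' Single-pole exponential smoothing of `|psi|` with per-sample smoothing
#' factor `alpha` (default 1/64): `nl <- (1 - alpha) * nl + alpha * |psi|`.
#' The low-pass attenuates short spike-driven excursions so the estimate
#' tracks the noise floor.
#'
#' @param psi_window window of NEO samples.
#' @param state previous noise level (scalar; `NULL` seeds the filter with the
#'   window mean, a deterministic warm start).
#' @param alpha smoothing factor per sample.
#' @return updated noise level (scalar, the filter state after the window).
#' @export
noise_estimate <- function(psi_window, state = NULL, alpha = 1 / 64) {
  if (length(psi_window) == 0) stopf("empty window")
  a <- abs(psi_window)
  if (is.null(state)) state <- mean(a)
  out <- stats::filter(alpha * a, 1 - alpha, method = "recursive",
                       init = state)
  as.numeric(out[length(out)])
}

#' Adaptive detection threshold
#'
#' Combines the noise estimate and the zero-crossing firing-rate proxy:
#' `threshold = max(floor_value, k * noise_level * (1 + beta * log_rate))`.
#' The form is monotone nondecreasing in both inputs and reduces to the
#' classic `k * noise` scaling at low firing rates.
#'
#' @param noise_level smoothed noise estimate (>= 0).
#' @param log_rate log2-scaled zero-crossing proxy.
#' @param k threshold multiplier (default 8).
#' @param beta rate sensitivity (default 0.125).
#' @param floor_value minimum threshold returned for degenerate (zero-noise)
#'   input (default 1).
#' @return scalar threshold.
#' @export
compute_threshold <- function(noise_level, log_rate = 0, k = 8, beta = 0.125,
                              floor_value = 1) {
  if (noise_level < 0) stopf("noise_level must be non-negative")
  max(floor_value, k * noise_level * (1 + beta * log_rate))
}

#' Adaptive threshold estimator configuration
#'
#' @param window_len samples per threshold update (default 64).
#' @param k_neo NEO-stage threshold multiplier.
#' @param k_amp amplitude-stage (stage 1) threshold multiplier.
#' @param beta rate sensitivity shared by both stages.
#' @param alpha noise-estimator smoothing factor.
#' @param floor_value threshold floor.
#' @return an `ate_config` list.
#' @export
ate_config <- function(window_len = 64, k_neo = 8, k_amp = 4, beta = 0.125,
                       alpha = 1 / 64, floor_value = 1) {
  structure(list(window_len = as.integer(window_len), k_neo = k_neo,
                 k_amp = k_amp, beta = beta, alpha = alpha,
                 floor_value = floor_value), class = "ate_config")
}

# Runs the full adaptive threshold estimator over one channel.  Thresholds
# are updated once per window from the statistics of the data seen so far
# (causal: the threshold applied in window w derives from windows < w, except
# the first window which warm-starts from its own mean).  Returns per-window
# thresholds for both stages plus the per-sample NEO series.
ate_run <- function(x, config = ate_config()) {
  n <- length(x)
  wl <- config$window_len
  psi <- c(0, neo(x), 0)        # align psi to sample indices, zero at edges
  n_win <- ceiling(n / wl)
  pad <- n_win * wl - n
  amat <- matrix(c(abs(psi), numeric(pad)), nrow = wl)   # |psi| per window
  xmat <- matrix(c(abs(as.numeric(x)), numeric(pad)), nrow = wl)
  # per-window EMA of |psi| and |x|: iterate the closed-form window update
  a <- config$alpha
  decay <- (1 - a)^wl
  # contribution of a window's samples to the EMA at the window end
  wts <- a * (1 - a)^((wl - 1):0)
  contrib_psi <- as.vector(wts %*% amat)
  contrib_amp <- as.vector(wts %*% xmat)
  nl_psi <- numeric(n_win); nl_amp <- numeric(n_win)
  s_psi <- mean(amat[, 1]); s_amp <- mean(xmat[, 1])     # warm start
  zc <- integer(n_win)
  neg <- psi < 0
  for (w in seq_len(n_win)) {
    i0 <- (w - 1L) * wl + 1L
    i1 <- min(w * wl, n)
    s_psi <- s_psi * decay + contrib_psi[w]
    s_amp <- s_amp * decay + contrib_amp[w]
    nl_psi[w] <- s_psi
    nl_amp[w] <- s_amp
    nw <- neg[i0:i1]
    zc[w] <- if (length(nw) > 1) sum(nw[-1] != nw[-length(nw)]) else 0L
  }
  log_rate <- floor(log2(zc + 1))
  # threshold applied in window w comes from the state after window w-1;
  # window 1 uses its own warm-start statistics
  lag1 <- function(v) c(v[1], v[-length(v)])
  thr_neo <- pmax(config$floor_value,
                  config$k_neo * lag1(nl_psi) * (1 + config$beta * lag1(log_rate)))
  thr_amp <- pmax(config$floor_value,
                  config$k_amp * lag1(nl_amp) * (1 + config$beta * lag1(log_rate)))
  list(psi = psi, thr_neo = thr_neo, thr_amp = thr_amp,
       noise_neo = nl_psi, noise_amp = nl_amp, zc_count = zc,
       log_rate = as.integer(log_rate), window_len = wl, n = n)
}

#' Two-stage spike detection
#'
#' Stage 1 flags candidate samples whose absolute amplitude exceeds an
#' adaptive amplitude threshold; stage 2 confirms candidates where the
#' absolute NEO output exceeds the adaptive NEO threshold.  Both thresholds
#' are re-estimated every `window_len` samples.  Each confirmed detection
#' emits a 64-sample event window with 32 samples before and 32 from the
#' detection instant onward (the instant is refined to the local NEO energy
#' peak within an 8-sample lookahead, so the pre-buffer captures the full
#' depolarization), and imposes a 64-sample refractory lockout between
#' detections on the channel.
#'
#' @param rec a [new_recording()].
#' @param channel channel id.
#' @param config an [ate_config()].
#' @return a `spike_events` object: list with `events` (data.frame `channel`,
#'   `onset`, `detect_index`) and `waveforms` (`n_events x 64` integer
#'   matrix of the raw recording samples at `[onset, onset + 64)`).
#' @export
detect_spikes <- function(rec, channel, config = ate_config()) {
  x <- rec_channel(rec, channel)
  n <- length(x)
  if (n < 64)
    return(structure(list(
      events = data.frame(channel = integer(), onset = integer(),
                          detect_index = integer()),
      waveforms = matrix(0L, 0, 64)), class = "spike_events"))
  run <- ate_run(x, config)
  wl <- run$window_len
  win_of <- rep(seq_along(run$thr_neo), each = wl, length.out = n)
  cand <- which(abs(as.numeric(x)) > run$thr_amp[win_of] &
                abs(run$psi) > run$thr_neo[win_of])
  cand <- cand[cand <= n - 31L]          # need 32 post-samples
  # refine each accepted crossing to the local NEO energy peak (8-sample
  # lookahead) so the 32-sample pre-buffer captures the full depolarization
  apsi <- abs(run$psi)
  det <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= 64) {
      j <- i - 1L + which.max(apsi[i:min(i + 7L, n - 31L)])
      det <- c(det, j)
      last <- j
    }
  }
  onset <- pmax(1L, det - 32L)
  onset <- pmin(onset, n - 63L)
  # edge clamping can shrink onset spacing below one window; re-impose the
  # lockout on onsets so event windows never overlap
  if (length(onset) > 1) {
    keep <- rep(TRUE, length(onset))
    last <- onset[1]
    for (j in seq_along(onset)[-1]) {
      if (onset[j] - last < 64L) keep[j] <- FALSE else last <- onset[j]
    }
    det <- det[keep]
    onset <- onset[keep]
  }
  wf <- matrix(0L, length(det), 64)
  for (j in seq_along(det)) wf[j, ] <- x[onset[j]:(onset[j] + 63L)]
  structure(list(
    events = data.frame(channel = rep(channel, length(det)),
                        onset = as.integer(onset),
                        detect_index = as.integer(det)),
    waveforms = wf), class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d event(s)\n", nrow(x$events)))
  invisible(x)
}

#' Match detections to ground truth
#'
#' A ground-truth spike counts as detected when some event onset lies within
#' `tol` samples of its onset; with the 64-sample refractory lockout, spikes
#' closer than one window to their predecessor are covered by the same event.
#'
#' @param events a `spike_events` object.
#' @param truth ground-truth data.frame with an `onset` column.
#' @param tol matching tolerance in samples (default 64, one event window).
#' @return list with `recall`, `n_matched`, `n_truth`, `n_events`.
#' @export
detection_recall <- function(events, truth, tol = 64) {
  if (nrow(truth) == 0)
    return(list(recall = NA_real_, n_matched = 0L, n_truth = 0L,
                n_events = nrow(events$events)))
  ons <- sort(events$events$onset)
  matched <- vapply(truth$onset, function(o) {
    length(ons) > 0 && min(abs(ons - o)) <= tol
  }, logical(1))
  list(recall = mean(matched), n_matched = sum(matched),
       n_truth = nrow(truth), n_events = nrow(events$events))
}
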