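#' Spike template waveforms
#'
#' A spike template is a 64-sample integer waveform in ADC counts.  The
#' parametric shape is a biphasic extracellular action potential: a short
#' baseline, a steep depolarization peaking near sample 33, a slower
#' repolarization trough and a decay back to baseline.  The depolarization is
#' placed 32 samples into the window, mirroring the detector's 32-sample
#' pre-buffer, so that an event window captured around the detection instant
#' coincides with the inserted template window.
#'
#' @param amplitude peak amplitude in ADC counts (positive).
#' @param width depolarization width factor (samples, roughly the rise time).
#' @param trough_frac depth of the repolarization trough relative to the peak.
#' @param template_id integer label carried into the ground truth.
#' @return a `spike_template`: list with `waveform` (64 integers) and
#'   `template_id`.
#' @export
spike_template <- function(amplitude = 80, width = 1.6, trough_frac = 0.45,
                           template_id = 1L) {
  t <- seq_len(64)
  peak_at <- 33
  trough_at <- peak_at + round(4 * width) + 3
  w <- amplitude * exp(-((t - peak_at)^2) / (2 * width^2)) -
    trough_frac * amplitude * exp(-((t - trough_at)^2) / (2 * (3 * width)^2))
  w[t < 26] <- 0
  w <- round(w)
  if (max(abs(w)) <= 0) stopf("template has zero peak amplitude")
  structure(list(waveform = as.integer(w), template_id = as.integer(template_id)),
            class = "spike_template")
}

#' Default template set
#'
#' Three units with distinct amplitudes and time courses, in the amplitude
#' regime of large nearby units on a 9-bit frontend (tens to ~100 counts).
#' @param n number of templates (1..3 distinct shapes are provided).
#' @return list of [spike_template()] objects.
#' @export
default_spike_templates <- function(n = 3) {
  shapes <- list(
    spike_template(amplitude = 80, width = 1.4, trough_frac = 0.45, template_id = 1L),
    spike_template(amplitude = 95, width = 2.2, trough_frac = 0.30, template_id = 2L),
    spike_template(amplitude = 65, width = 1.1, trough_frac = 0.70, template_id = 3L))
  shapes[seq_len(min(n, 3))]
}

#' Generator configuration
#'
#' Defaults follow the frontend operating point modeled throughout the
#' package: 20 kHz sampling, 9-bit samples, an aggregate firing rate of
#' 60 spikes/s per channel (20 Hz for each of the three default templates),
#' and a background noise standard deviation of 2 ADC counts (about 8 uV rms
#' at a 3.9 uV LSB).
#'
#' @param n_channels number of channels.
#' @param duration_s recording length in seconds.
#' @param firing_rate_hz Poisson firing rate per template (recycled across
#'   templates); the aggregate channel rate is the sum over templates.
#' @param noise_sd background noise standard deviation, ADC counts.
#' @param lfp_amplitude standard deviation of the low-frequency field
#'   component, ADC counts (0 disables it; the action-potential band is
#'   high-pass filtered in hardware, so AP-regime fixtures use 0).
#' @param lfp_spatial_mixing inter-channel LFP correlation parameter in
#'   `[0, 1]`; channel weights decay as `mixing^|c - j|`.
#' @param fs sampling frequency, Hz.
#' @param bit_depth bits per sample.
#' @param seed integer seed fixing all randomness.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_channels = 1, duration_s = 1,
                             firing_rate_hz = 20, noise_sd = 2,
                             lfp_amplitude = 0, lfp_spatial_mixing = 0.9,
                             fs = 20000, bit_depth = 9, seed = 1L) {
  if (any(firing_rate_hz < 0)) stopf("firing rates must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (lfp_amplitude < 0) stopf("lfp_amplitude must be non-negative")
  if (lfp_spatial_mixing < 0 || lfp_spatial_mixing > 1)
    stopf("lfp_spatial_mixing must be in [0, 1]")
  if (bit_depth < 2 || bit_depth > 16) stopf("invalid bit depth")
  structure(list(n_channels = as.integer(n_channels), duration_s = duration_s,
                 firing_rate_hz = firing_rate_hz, noise_sd = noise_sd,
                 lfp_amplitude = lfp_amplitude,
                 lfp_spatial_mixing = lfp_spatial_mixing,
                 fs = fs, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# band-limited (< cutoff Hz) unit-variance noise, one series per row
lfp_noise <- function(n_rows, n, fs, cutoff = 300) {
  if (n < 32) return(matrix(rnorm(n_rows * n), nrow = n_rows))
  bf <- signal::butter(4, min(cutoff / (fs / 2), 0.99), type = "low")
  out <- matrix(0, n_rows, n)
  for (i in seq_len(n_rows)) {
    x <- signal::filtfilt(bf, rnorm(n))
    s <- sd(x)
    out[i, ] <- if (s > 0) x / s else x
  }
  out
}

#' Generate a synthetic multichannel extracellular recording
#'
#' Superimposes Poisson spike trains of the given templates, additive Gaussian
#' background noise, and a spatially correlated low-frequency field component,
#' then quantizes to the configured bit depth.  Each channel and template pair
#' is an independent Poisson process.  Overlapping spikes superimpose; the
#' ground truth records every inserted onset.
#'
#' @param config a [generator_config()].
#' @param templates list of [spike_template()]s (required when any firing rate
#'   is positive).
#' @return list with `recording` (a [new_recording()]) and `ground_truth`, a
#'   data.frame with columns `channel`, `onset`, `template_id` (onset is the
#'   1-based index of the first sample of the 64-sample template window).
#' @export
generate_recording <- function(config, templates = default_spike_templates()) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(round(config$duration_s * config$fs))
  C <- config$n_channels
  rates <- config$firing_rate_hz
  if (any(rates > 0) && length(templates) == 0)
    stopf("templates required when firing rate is positive")
  with_seed(config$seed, {
    x <- matrix(0, C, n)
    truth <- list()
    if (length(templates) > 0 && n >= 64) {
      rates <- rep_len(rates, length(templates))
      for (ch in seq_len(C)) {
        for (ti in seq_along(templates)) {
          if (rates[ti] <= 0) next
          n_sp <- rpois(1, rates[ti] * config$duration_s)
          if (n_sp == 0) next
          onsets <- sort(sample.int(n - 64L + 1L, n_sp, replace = TRUE))
          w <- templates[[ti]]$waveform
          for (o in onsets) x[ch, o:(o + 63L)] <- x[ch, o:(o + 63L)] + w
          truth[[length(truth) + 1L]] <- data.frame(
            channel = ch, onset = onsets,
            template_id = templates[[ti]]$template_id)
        }
      }
    }
    if (config$noise_sd > 0)
      x <- x + matrix(rnorm(C * n, sd = config$noise_sd), C, n)
    if (config$lfp_amplitude > 0 && n > 0) {
      u <- lfp_noise(C, n, config$fs)
      m <- config$lfp_spatial_mixing
      W <- m^abs(outer(seq_len(C), seq_len(C), "-"))
      W <- W / sqrt(rowSums(W^2))          # unit-variance mixtures
      x <- x + config$lfp_amplitude * (W %*% u)
    }
    samples <- quantize_counts(x, config$bit_depth)
    gt <- if (length(truth)) do.call(rbind, truth) else
      data.frame(channel = integer(), onset = integer(), template_id = integer())
    gt <- gt[order(gt$channel, gt$onset), , drop = FALSE]
    rownames(gt) <- NULL
    list(recording = new_recording(samples, fs = config$fs,
                                   bit_depth = config$bit_depth),
         ground_truth = gt)
  })
}

#' Correlated parent/child LFP pair fixture
#'
#' Generates a band-limited parent series and a child that is
#' `gamma_true * parent` plus independent noise, both rounded to integer
#' counts.  Used to validate recovery of the spatial decorrelation factor.
#'
#' @param n series length (at least 100).
#' @param gamma_true true mixing coefficient.
#' @param seed RNG seed.
#' @param amplitude parent standard deviation in ADC counts.
#' @param noise_sd child-side independent noise, ADC counts.
#' @param fs sampling rate used for the band limit.
#' @return list with integer vectors `parent` and `child`.
#' @export
generate_lfp_pair <- function(n, gamma_true, seed = 1L, amplitude = 100,
                              noise_sd = 1, fs = 20000) {
  if (n < 100) stopf("n must be at least 100")
  with_seed(seed, {
    parent <- round(amplitude * as.vector(lfp_noise(1, n, fs)))
    child <- round(gamma_true * parent + rnorm(n, sd = noise_sd))
    list(parent = as.integer(parent), child = as.integer(child))
  })
}
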