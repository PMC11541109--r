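FIR_TAPS <- 16L
FIR_SAT_MAX <-  2^25 - 1     # 26-bit signed accumulator bounds
FIR_SAT_MIN <- -2^25

#' Fixed-point FIR filter (16 taps, 26-bit saturating accumulator)
#'
#' `y[n] = sat26( sum_{i=0..15} c[i] * x[n-i] )` with zero pre-history.
#' Coefficients are signed 16-bit integers; inputs are 9-bit frontend
#' samples, so every product and the full 16-term sum are exact in double
#' precision and saturation applies only to the final accumulated sum, at
#' `+2^25 - 1` / `-2^25`.
#'
#' @param x integer sample series (signed 9-bit range).
#' @param coeffs 16 signed integers within `[-2^15, 2^15 - 1]`,
#'   `c[1]` multiplying the current sample.
#' @return numeric vector of saturated filter outputs, same length as `x`.
#' @export
fir_filter <- function(x, coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != FIR_TAPS)
    stopf("exactly %d coefficients required", FIR_TAPS)
  if (any(coeffs < -2^15 | coeffs > 2^15 - 1))
    stopf("coefficients exceed the signed 16-bit range")
  x <- as.numeric(x)
  if (length(x) && (max(x) > 2^8 - 1 || min(x) < -2^8))
    stopf("input samples exceed the signed 9-bit range")
  if (length(x) == 0) return(numeric(0))
  xp <- c(numeric(FIR_TAPS - 1), x)
  y <- as.vector(stats::embed(xp, FIR_TAPS) %*% coeffs)
  pmin(FIR_SAT_MAX, pmax(FIR_SAT_MIN, y))
}

#' Parallel FIR filtering of up to 16 channels
#'
#' Applies [fir_filter()] channel-wise; each of the at most 16 selected
#' channels gets its own coefficient set.
#'
#' @param rec a [new_recording()].
#' @param coeffs a 16-vector (shared by all channels) or a list / 16-row
#'   matrix of per-channel coefficient sets.
#' @param channels channel ids to filter (default all; at most 16).
#' @return list with `y`, a `length(channels) x n` numeric matrix of filter
#'   outputs (raw saturated 26-bit sums, no output scaling), and `channels`.
#' @export
filterbank <- function(rec, coeffs, channels = rec$channel_ids) {
  if (length(channels) > FIR_TAPS)
    stopf("the filterbank processes at most 16 channels in parallel")
  get_c <- function(i) {
    if (is.matrix(coeffs)) coeffs[, i]
    else if (is.list(coeffs)) coeffs[[i]]
    else coeffs
  }
  y <- t(vapply(seq_along(channels), function(i)
    fir_filter(rec_channel(rec, channels[i]), get_c(i)),
    numeric(ncol(rec$samples))))
  list(y = y, channels = channels)
}

#' Integer low-pass FIR design helper
#'
#' Windowed-sinc low-pass prototype quantized to signed 16-bit integer taps,
#' convenient for LFP extraction with the fixed-point filterbank.
#'
#' @param cutoff_hz cutoff frequency.
#' @param fs sampling rate.
#' @param scale integer full-scale of the quantized taps (default `2^14`).
#' @return 16 integer coefficients.
#' @export
fir_lowpass_coeffs <- function(cutoff_hz, fs = 20000, scale = 2^14) {
  n <- seq_len(FIR_TAPS) - 1
  m <- (FIR_TAPS - 1) / 2
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * (n - m)) * hamming_win(FIR_TAPS)
  q <- round(h / sum(h) * scale)
  as.integer(pmin(2^15 - 1, pmax(-2^15, q)))
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
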