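#' Multichannel integer recording container
#'
#' A `neuro_recording` holds a channels-by-time integer sample matrix together
#' with its sampling rate and ADC bit depth.  Samples are stored in ADC counts
#' and must lie inside the signed range of the declared bit depth.
#'
#' @param samples integer matrix, channels in rows, time in columns.
#' @param fs sampling frequency in Hz.
#' @param bit_depth bits per sample (signed); every sample must satisfy
#'   `-2^(bit_depth-1) <= s <= 2^(bit_depth-1) - 1`.
#' @param channel_ids optional integer channel labels (default `1:n_channels`).
#'
#' @return an object of class `neuro_recording` with fields `samples`, `fs`,
#'   `bit_depth`, `channel_ids`.
#' @export
new_recording <- function(samples, fs = 20000, bit_depth = 9,
                          channel_ids = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  storage.mode(samples) <- "integer"
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(samples))
  rec <- structure(
    list(samples = samples, fs = fs, bit_depth = as.integer(bit_depth),
         channel_ids = as.integer(channel_ids)),
    class = "neuro_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (rec$fs <= 0) stopf("sampling frequency must be positive")
  if (rec$bit_depth < 2 || rec$bit_depth > 16)
    stopf("bit_depth must be in [2, 16]")
  if (length(rec$channel_ids) != nrow(rec$samples))
    stopf("channel_ids length must match the number of channel rows")
  if (ncol(rec$samples) > 0) {
    lo <- -bit_range(rec$bit_depth) - 1L
    hi <- bit_range(rec$bit_depth)
    rng <- range(rec$samples)
    if (rng[1] < lo || rng[2] > hi)
      stopf("samples exceed the signed %d-bit range [%d, %d]",
            rec$bit_depth, lo, hi)
  }
  invisible(rec)
}

# largest positive value of a signed b-bit integer
bit_range <- function(b) as.integer(2^(b - 1) - 1)

# clip-and-round a numeric matrix/vector into the signed bit_depth range
quantize_counts <- function(x, bit_depth) {
  hi <- bit_range(bit_depth)
  lo <- -hi - 1L
  x <- round(x)
  x[x > hi] <- hi
  x[x < lo] <- lo
  storage.mode(x) <- "integer"
  x
}

#' @export
print.neuro_recording <- function(x, ...) {
  cat(sprintf("<neuro_recording> %d channel(s) x %d samples @ %g Hz, %d-bit\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$bit_depth))
  invisible(x)
}

#' @export
dim.neuro_recording <- function(x) dim(x$samples)

rec_channel <- function(rec, channel) {
  i <- match(channel, rec$channel_ids)
  if (is.na(i)) stopf("unknown channel id: %s", channel)
  rec$samples[i, ]
}

#' Write / read a recording as raw binary plus JSON sidecar
#'
#' The payload is little-endian signed 16-bit, channel-interleaved (all
#' channels of sample 1, then sample 2, ...).  The sidecar `<path>.json`
#' carries `n_channels`, `fs_hz`, `bit_depth`, `dtype`, `byte_order` and
#' `channel_ids`, so a recording round-trips exactly.
#'
#' @param rec a [new_recording()] object.
#' @param path file path of the binary payload; the sidecar is written next to
#'   it as `paste0(path, ".json")`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `neuro_recording`.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  meta <- list(n_channels = nrow(rec$samples), fs_hz = rec$fs,
               bit_depth = rec$bit_depth, dtype = "int16",
               byte_order = "little", channel_ids = rec$channel_ids)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  # column-major write of the [channels x time] matrix = channel-interleaved
  writeBin(as.integer(rec$samples), con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing sidecar metadata file: %s", sidecar)
  if (!file.exists(path)) stopf("missing payload file: %s", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_bytes <- file.size(path)
  if (n_bytes %% 2 != 0) stopf("truncated payload: odd byte count")
  n_vals <- n_bytes / 2
  if (meta$n_channels > 0 && n_vals %% meta$n_channels != 0)
    stopf("payload length %d not divisible by channel count %d",
          n_vals, meta$n_channels)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "integer", n = n_vals, size = 2L, signed = TRUE,
                  endian = "little")
  samples <- matrix(vals, nrow = meta$n_channels)
  new_recording(samples, fs = meta$fs_hz, bit_depth = meta$bit_depth,
                channel_ids = meta$channel_ids)
}
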