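#' Spike-raster packetization
#'
#' One frame per sampling tick: the detection bits of all channels are OR-ed;
#' a tick with no detection yields a header-only (empty) frame, otherwise the
#' frame lists the firing channel ids with the tick index.  The frame count
#' always equals the tick count.
#'
#' @param detections logical/0-1 matrix, `ticks x channels`.
#' @return a `raster_frames` object: list with `n_ticks`, `channels` (number
#'   of channels) and `firing`, a list of integer channel-id vectors per tick
#'   (empty vectors for empty frames).
#' @export
make_raster <- function(detections) {
  if (!is.matrix(detections)) detections <- matrix(detections, ncol = 1)
  firing <- lapply(seq_len(nrow(detections)), function(t)
    which(detections[t, ] != 0))
  structure(list(n_ticks = nrow(detections), channels = ncol(detections),
                 firing = firing),
            class = "raster_frames")
}

#' @export
print.raster_frames <- function(x, ...) {
  cat(sprintf("<raster_frames> %d tick(s), %d non-empty\n", x$n_ticks,
              sum(lengths(x$firing) > 0)))
  invisible(x)
}

RASTER_HDR_EMPTY <- as.raw(0xA0)
RASTER_HDR_FIRING <- as.raw(0xA1)

#' Serialize / parse raster frames as byte packets
#'
#' Wire format per tick: 1 header byte (`0xA0` empty, `0xA1` firing); firing
#' frames append the tick index (unsigned 32-bit little-endian), a channel
#' count byte and one byte per firing channel id.
#'
#' @param frames a [make_raster()] object.
#' @return `encode_raster_packets`: a raw vector.
#' @export
encode_raster_packets <- function(frames) {
  stopifnot(inherits(frames, "raster_frames"))
  parts <- lapply(seq_len(frames$n_ticks), function(t) {
    ch <- frames$firing[[t]]
    if (length(ch) == 0) return(RASTER_HDR_EMPTY)
    c(RASTER_HDR_FIRING,
      writeBin(as.integer(t - 1L), raw(), size = 4L, endian = "little"),
      as.raw(length(ch)), as.raw(ch - 1L))
  })
  do.call(c, parts)
}

#' @rdname encode_raster_packets
#' @param bytes raw vector from `encode_raster_packets`.
#' @param channels number of channels represented in the frames.
#' @export
decode_raster_packets <- function(bytes, channels) {
  firing <- list()
  p <- 1L
  while (p <= length(bytes)) {
    if (bytes[p] == RASTER_HDR_EMPTY) {
      firing[[length(firing) + 1L]] <- integer(0)
      p <- p + 1L
    } else if (bytes[p] == RASTER_HDR_FIRING) {
      tick <- readBin(bytes[(p + 1L):(p + 4L)], "integer", size = 4L,
                      endian = "little")
      if (tick != length(firing)) stopf("raster packet tick out of order")
      nch <- as.integer(bytes[p + 5L])
      ch <- as.integer(bytes[(p + 6L):(p + 5L + nch)]) + 1L
      firing[[length(firing) + 1L]] <- ch
      p <- p + 6L + nch
    } else stopf("unknown raster packet header byte")
  }
  structure(list(n_ticks = length(firing), channels = channels,
                 firing = firing),
            class = "raster_frames")
}

# detection-bit matrix [ticks x channels] for a recording: 1 at each
# detection instant
detection_bits <- function(rec, config = ate_config()) {
  n <- ncol(rec$samples)
  det <- matrix(0L, n, length(rec$channel_ids))
  for (i in seq_along(rec$channel_ids)) {
    ev <- detect_spikes(rec, rec$channel_ids[i], config)
    det[ev$events$detect_index, i] <- 1L
  }
  det
}
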