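#' Second-order DPCM decorrelation
#'
#' Predicts each sample from its two predecessors; the residual is the second
#' difference `r[i] = s[i] - 2 s[i-1] + s[i-2]`.  The first two raw samples
#' are kept as warm-up so decoding is exact.  On band-limited neural signals
#' the residual distribution is far more concentrated than the raw samples,
#' which is what the entropy coders exploit.
#'
#' @param s integer sample series of length at least 2.
#' @return a `residual_stream`: list with `warmup` (first two raw samples) and
#'   `residuals` (length `length(s) - 2`).
#' @export
dpcm2_encode <- function(s) {
  if (length(s) < 2) stopf("series must have at least 2 samples")
  s <- as.integer(s)
  structure(list(warmup = s[1:2],
                 residuals = if (length(s) > 2) diff(diff(s)) else integer(0)),
            class = "residual_stream")
}

#' @rdname dpcm2_encode
#' @param r a `residual_stream`.
#' @return `dpcm2_decode`: the original integer series, exactly.
#' @export
dpcm2_decode <- function(r) {
  stopifnot(inherits(r, "residual_stream"))
  w <- as.numeric(r$warmup)
  as.integer(cumsum(c(w[1], cumsum(c(w[2] - w[1], as.numeric(r$residuals))))))
}

# DPCM2 with an all-zero history, used inside near-lossless frames so each
# 64-sample spike decodes independently of its neighbours.
dpcm2_zero_history <- function(s) {
  s <- as.numeric(s)
  n <- length(s)
  prev1 <- c(0, s[-n])
  prev2 <- c(0, 0, s[-c(n - 1, n)])[1:n]
  as.integer(s - 2 * prev1 + prev2)
}

dpcm2_zero_history_inv <- function(r) {
  n <- length(r)
  s <- numeric(n)
  p1 <- 0; p2 <- 0
  for (i in seq_len(n)) {
    s[i] <- r[i] + 2 * p1 - p2
    p2 <- p1; p1 <- s[i]
  }
  as.integer(s)
}

RLE_COMPONENT_BITS <- 8L   # bitwise split width of a zero-run length

# split a zero-run length into 2 components (runs < 2^16) or 3 (larger),
# most significant first; the per-frame flag says which
rle_split <- function(run) {
  w <- RLE_COMPONENT_BITS
  if (run < 2^(2 * w)) {
    list(flag = 0L, comps = c(run %/% 2^w, run %% 2^w))
  } else {
    if (run >= 2^(3 * w)) stopf("zero run too long for 3-component split")
    list(flag = 1L,
         comps = c(run %/% 2^(2 * w), (run %/% 2^w) %% 2^w, run %% 2^w))
  }
}

rle_join <- function(comps) {
  w <- RLE_COMPONENT_BITS
  as.integer(sum(comps * 2^(w * (length(comps):1 - 1))))
}

backend_encode <- function(symbols, backend, table, k_init = 3L) {
  if (backend == "gc") rice_adaptive_encode(symbols, k_init = k_init)
  else ac_encode(symbols, table)
}

backend_decode <- function(bits, backend, table, n, k_init = 3L) {
  if (backend == "gc") rice_adaptive_decode(bits, n, k_init = k_init)$values
  else ac_decode(bits, table, n)
}

#' Compress one channel of a recording
#'
#' Lossless mode codes the whole sample stream: DPCM2 decorrelation, zigzag
#' mapping to non-negative values, then the chosen entropy backend (`"gc"`,
#' block-adaptive Golomb-Rice; or `"ac"`, arithmetic coding with a shared
#' frozen symbol table).  Near-lossless mode keeps only the detected
#' 64-sample spike windows and their timing: the stream becomes alternating
#' frames of (zero-run length, spike), the run length split bitwise into 2 or
#' 3 eight-bit components selected by a per-frame flag bit, and the spike
#' samples DPCM2-coded within the frame; everything between spikes decodes to
#' zero.
#'
#' @param rec a [new_recording()].
#' @param channel channel id.
#' @param mode `"lossless"` or `"near_lossless"`.
#' @param backend `"gc"` or `"ac"`.
#' @param events a `spike_events` object from [detect_spikes()]; required in
#'   near-lossless mode.
#' @param table optional pre-trained [train_symbol_table()]; when `NULL` and
#'   `backend = "ac"`, a table is trained on this channel's mapped symbols.
#' @param k_init initial Rice parameter for the `"gc"` backend.
#' @return a `neuro_bitstream`: list with `header` (mode, backend, channel,
#'   `n_samples`, `bit_depth`, warm-up samples, event count), `flags`
#'   (near-lossless frame flag bits), `bits` (entropy-coded payload),
#'   `table` (the symbol table, AC only), `n_symbols`, and `payload_nbits`
#'   (flag + payload + warm-up bits; headers and the shared table excluded,
#'   the default space-saving-ratio accounting).
#' @export
compress_channel <- function(rec, channel,
                             mode = c("lossless", "near_lossless"),
                             backend = c("gc", "ac"),
                             events = NULL, table = NULL, k_init = 3L) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  x <- rec_channel(rec, channel)
  n <- length(x)
  if (mode == "lossless") {
    rs <- dpcm2_encode(x)
    symbols <- map_to_nonneg(rs$residuals)
    if (backend == "ac" && is.null(table)) table <- train_symbol_table(symbols)
    bits <- backend_encode(symbols, backend, table, k_init)
    warm_bits <- 2L * 16L
    header <- list(mode = mode, backend = backend, channel = channel,
                   n_samples = n, bit_depth = rec$bit_depth,
                   warmup = rs$warmup, n_events = 0L)
    flags <- integer(0)
  } else {
    if (is.null(events)) stopf("near-lossless mode requires detected events")
    ev <- events$events
    wf <- events$waveforms
    if (nrow(ev) > 1) {
      keep <- rep(TRUE, nrow(ev))
      last <- ev$onset[1]
      for (i in seq_len(nrow(ev))[-1]) {
        if (ev$onset[i] - last < 64) keep[i] <- FALSE else last <- ev$onset[i]
      }
      ev <- ev[keep, , drop = FALSE]
      wf <- wf[keep, , drop = FALSE]
    }
    symbols <- integer(0)
    flags <- integer(nrow(ev))
    pos <- 1L
    sym_list <- vector("list", nrow(ev))
    for (i in seq_len(nrow(ev))) {
      run <- ev$onset[i] - pos
      sp <- rle_split(run)
      flags[i] <- sp$flag
      resid <- dpcm2_zero_history(wf[i, ])
      sym_list[[i]] <- c(sp$comps, map_to_nonneg(resid))
      pos <- ev$onset[i] + 64L
    }
    symbols <- as.integer(unlist(sym_list))
    if (backend == "ac" && is.null(table))
      table <- train_symbol_table(if (length(symbols)) symbols else 0L)
    bits <- if (length(symbols)) backend_encode(symbols, backend, table, k_init)
            else integer(0)
    warm_bits <- 0L
    header <- list(mode = mode, backend = backend, channel = channel,
                   n_samples = n, bit_depth = rec$bit_depth,
                   warmup = integer(0), n_events = nrow(ev))
  }
  structure(list(header = header, flags = flags, bits = bits, table = table,
                 k_init = as.integer(k_init),
                 n_symbols = length(symbols),
                 payload_nbits = length(bits) + length(flags) + warm_bits),
            class = "neuro_bitstream")
}

#' @export
print.neuro_bitstream <- function(x, ...) {
  cat(sprintf("<neuro_bitstream> %s/%s, channel %s: %d samples -> %d bits\n",
              x$header$mode, x$header$backend, x$header$channel,
              x$header$n_samples, x$payload_nbits))
  invisible(x)
}

#' Decompress an intra-channel bitstream
#'
#' Exact inverse of [compress_channel()].  Lossless streams reconstruct every
#' sample; near-lossless streams reconstruct each spike's 64-sample window at
#' its exact onset and zeros elsewhere.
#'
#' @param bs a `neuro_bitstream`.
#' @param table symbol table override (defaults to the one carried in `bs`).
#' @return list with `samples` (integer vector of length `n_samples`) and,
#'   for near-lossless streams, `events` (data.frame `onset` per spike).
#' @export
decompress_channel <- function(bs, table = NULL) {
  stopifnot(inherits(bs, "neuro_bitstream"))
  h <- bs$header
  if (is.null(table)) table <- bs$table
  if (h$mode == "lossless") {
    n_res <- h$n_samples - 2L
    symbols <- backend_decode(bs$bits, h$backend, table, n_res, bs$k_init)
    rs <- structure(list(warmup = h$warmup,
                         residuals = map_from_nonneg(symbols)),
                    class = "residual_stream")
    list(samples = dpcm2_decode(rs))
  } else {
    n_ev <- h$n_events
    samples <- integer(h$n_samples)
    onsets <- integer(n_ev)
    if (n_ev > 0) {
      n_sym <- sum(ifelse(bs$flags == 1L, 3L, 2L) + 64L)
      symbols <- backend_decode(bs$bits, h$backend, table, n_sym, bs$k_init)
      pos <- 1L; sp <- 1L
      for (i in seq_len(n_ev)) {
        nc <- if (bs$flags[i] == 1L) 3L else 2L
        run <- rle_join(symbols[sp:(sp + nc - 1L)])
        sp <- sp + nc
        resid <- map_from_nonneg(symbols[sp:(sp + 63L)])
        sp <- sp + 64L
        onset <- pos + run
        samples[onset:(onset + 63L)] <- dpcm2_zero_history_inv(resid)
        onsets[i] <- onset
        pos <- onset + 64L
      }
    }
    list(samples = samples, events = data.frame(onset = onsets))
  }
}

#' Space saving ratio
#'
#' `100 * (1 - compressed_bits / original_bits)`, the standard compression
#' figure of merit; the uncompressed size of a recording is
#' `n_samples * bit_depth` bits.
#'
#' @param original_bits uncompressed size in bits (> 0).
#' @param compressed_bits compressed size in bits.
#' @return percentage.
#' @export
ssr <- function(original_bits, compressed_bits) {
  if (original_bits <= 0) stopf("original_bits must be positive")
  100 * (1 - compressed_bits / original_bits)
}

#' @rdname ssr
#' @param bs a `neuro_bitstream` from [compress_channel()].
#' @return `ssr_of`: the stream's SSR against `n_samples * bit_depth` raw
#'   bits, headers excluded.
#' @export
ssr_of <- function(bs) {
  ssr(bs$header$n_samples * bs$header$bit_depth, bs$payload_nbits)
}
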