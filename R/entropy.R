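#' Zigzag mapping of signed integers to naturals
#'
#' Interleaves signs so small-magnitude residuals get small codes:
#' `0 -> 0, -1 -> 1, 1 -> 2, -2 -> 3, 2 -> 4, ...`.  Bijective; the prefix
#' codes downstream require non-negative input and reward small values.
#'
#' @param v integer vector (any sign).
#' @return non-negative integer vector of the same length.
#' @export
map_to_nonneg <- function(v) {
  v <- as.integer(v)
  ifelse(v >= 0L, 2L * v, -2L * v - 1L)
}

#' @rdname map_to_nonneg
#' @param m non-negative integer vector.
#' @export
map_from_nonneg <- function(m) {
  m <- as.integer(m)
  ifelse(m %% 2L == 0L, m %/% 2L, -(m + 1L) %/% 2L)
}

#' Golomb-Rice coding
#'
#' Rice code with divisor `M = 2^k`: the quotient `v %/% M` in unary (`q` one
#' bits then a zero), the remainder in `k` bits MSB-first.  Optimal for
#' geometric sources when `k` is matched to the mean.
#'
#' @param values non-negative integer vector.
#' @param k Rice parameter in `[0, 30]`.
#' @return `golomb_encode`: integer vector of bits (0/1).
#' @export
golomb_encode <- function(values, k) {
  .rice_encode_cpp(as.integer(values), as.integer(k))
}

#' @rdname golomb_encode
#' @param bits bit vector (0/1).
#' @param n number of values to decode.
#' @param start 0-based bit offset at which decoding begins.
#' @return `golomb_decode`: list with `values` and `next` (offset of the first
#'   unread bit).
#' @export
golomb_decode <- function(bits, k, n, start = 0L) {
  .rice_decode_cpp(as.integer(bits), as.integer(k), as.integer(n),
                   as.integer(start))
}

# Rice-parameter lookup thresholds on the running zero fraction.  Derived
# from the geometric-source optimum 2^k ~ mean * ln 2 with mean = (1-zf)/zf:
# higher zero fraction (peakier source) -> smaller k.
rice_zf_thresholds <- c(0.329, 0.197, 0.109, 0.0578, 0.0297, 0.0151, 0.0076)

#' Rice parameter from the running zero fraction
#'
#' Monotone 8-level lookup mapping the proportion of zero samples in the
#' recent past to a Rice parameter: all-zero sources get `k = 0`, zero-free
#' sources get the table maximum `k = 7`.
#'
#' @param zero_fraction proportion of zero samples in `[0, 1]`.
#' @return integer `k` in `[0, 7]`.
#' @export
adapt_rice_parameter <- function(zero_fraction) {
  if (any(zero_fraction < 0 | zero_fraction > 1))
    stopf("zero_fraction must lie in [0, 1]")
  vapply(zero_fraction,
         function(zf) sum(zf < rice_zf_thresholds), numeric(1)) |> as.integer()
}

# Block-adaptive Rice coding of a non-negative symbol stream: the stream is
# chunked into `window`-symbol blocks; each block is coded with the k chosen
# from the zero fraction of the previous block (k_init for the first).  The
# decoder mirrors the adaptation from its own decoded output, so no side
# information is needed.
rice_adaptive_encode <- function(values, k_init = 3L, window = 256L) {
  n <- length(values)
  if (n == 0) return(integer(0))
  starts <- seq(1L, n, by = window)
  k <- as.integer(k_init)
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    idx <- starts[b]:min(starts[b] + window - 1L, n)
    out[[b]] <- golomb_encode(values[idx], k)
    k <- adapt_rice_parameter(mean(values[idx] == 0L))
  }
  unlist(out)
}

rice_adaptive_decode <- function(bits, n, k_init = 3L, window = 256L,
                                 start = 0L) {
  if (n == 0) return(list(values = integer(0), `next` = start))
  k <- as.integer(k_init)
  pos <- start
  left <- n
  out <- vector("list", ceiling(n / window))
  b <- 1L
  while (left > 0) {
    m <- min(window, left)
    dec <- golomb_decode(bits, k, m, pos)
    out[[b]] <- dec$values
    pos <- dec$`next`
    k <- adapt_rice_parameter(mean(dec$values == 0L))
    left <- left - m
    b <- b + 1L
  }
  list(values = unlist(out), `next` = pos)
}

# --------------------------------------------------------------------------
# Semi-adaptive arithmetic coding: a frozen symbol table trained offline.

AC_ALPHABET <- 1023L    # explicit symbols 0..1022; index 1023 is the escape
AC_TABLE_TOTAL <- 32768L

#' Train a shared symbol table for the arithmetic coder
#'
#' Builds frequency counts of mapped residuals over the explicit alphabet
#' `0..1022`; larger values are pooled into an escape symbol (coded as escape
#' plus a 12-bit literal).  Counts are quantized to 16-bit with a floor of 1
#' so the serialized table fits the 2048-byte budget (1024 symbols x 2
#' bytes).  Training is deterministic for fixed input.
#'
#' @param streams a non-negative integer vector, or a list of them (e.g.
#'   mapped residual streams from several channels sharing one table).
#' @return a `symbol_table`: list with integer `counts` (length 1024, escape
#'   last), `cum` (cumulative counts, length 1025) and `total`.
#' @export
train_symbol_table <- function(streams) {
  if (!is.list(streams)) streams <- list(streams)
  v <- unlist(streams, use.names = FALSE)
  if (length(v) < 1) stopf("cannot train a symbol table on empty input")
  v <- as.integer(v)
  if (any(v < 0)) stopf("symbol streams must be non-negative (mapped) values")
  sym <- pmin(v, AC_ALPHABET)            # >= 1023 pools into escape
  raw_counts <- tabulate(sym + 1L, nbins = AC_ALPHABET + 1L)
  counts <- pmax(1L, as.integer(round(raw_counts / sum(raw_counts) *
                                        (AC_TABLE_TOTAL - AC_ALPHABET - 1L))))
  structure(list(counts = counts,
                 cum = c(0L, cumsum(counts)),
                 total = sum(counts)),
            class = "symbol_table")
}

#' Serialize a symbol table (2 KiB layout)
#'
#' @param table a [train_symbol_table()] result.
#' @return raw vector of exactly 2048 bytes (1024 unsigned 16-bit counts,
#'   little-endian).
#' @export
serialize_symbol_table <- function(table) {
  stopifnot(inherits(table, "symbol_table"))
  writeBin(as.integer(table$counts), raw(), size = 2L, endian = "little")
}

#' @rdname serialize_symbol_table
#' @param bytes raw vector from `serialize_symbol_table`.
#' @export
deserialize_symbol_table <- function(bytes) {
  counts <- readBin(bytes, "integer", n = length(bytes) / 2, size = 2L,
                    signed = FALSE, endian = "little")
  structure(list(counts = as.integer(counts),
                 cum = c(0L, cumsum(as.integer(counts))),
                 total = sum(counts)),
            class = "symbol_table")
}

#' Arithmetic coding with a frozen symbol table
#'
#' Integer range coder (32-bit, carry handled by bits-plus-follow) over the
#' trained table; values above the explicit alphabet are coded as the escape
#' symbol followed by a 12-bit literal.  Decoding inverts exactly given the
#' same table and the number of values.
#'
#' @param values non-negative integer vector (each below 4096).
#' @param table a [train_symbol_table()] result.
#' @return `ac_encode`: bit vector (0/1).
#' @export
ac_encode <- function(values, table) {
  stopifnot(inherits(table, "symbol_table"))
  .ac_encode_cpp(as.integer(values), table$cum)
}

#' @rdname ac_encode
#' @param bits bit vector.
#' @param n number of values to decode.
#' @export
ac_decode <- function(bits, table, n) {
  stopifnot(inherits(table, "symbol_table"))
  .ac_decode_cpp(as.integer(bits), table$cum, as.integer(n))
}
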