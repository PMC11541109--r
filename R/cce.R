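#' First-order temporal decorrelation (DPCM)
#'
#' `e[i] = s[i] - s[i-1]` with `e[1] = s[1]`; exact inverse by cumulative
#' sum.  This is the temporal stage of the cross-channel codec.
#'
#' @param x integer series.
#' @return integer residual series of the same length.
#' @export
temporal_decorrelate <- function(x) {
  x <- as.integer(x)
  if (length(x) == 0) return(integer(0))
  as.integer(c(x[1], diff(x)))
}

#' @rdname temporal_decorrelate
#' @param e residual series from `temporal_decorrelate`.
#' @export
temporal_recorrelate <- function(e) {
  as.integer(cumsum(as.numeric(e)))
}

#' Spatial decorrelation factor (closed form)
#'
#' Least-squares coefficient predicting the child's temporal residuals from
#' the parent's over the training segment `[n0, N]`:
#' `gamma = sum(e_c * e_r) / sum(e_r^2)`.  This is the minimizer of the
#' residual energy, which is the proxy for coding length.
#'
#' @param e_c child residual series.
#' @param e_r parent (reference) residual series.
#' @param n0 first sample of the training segment (1-based).
#' @param N last sample of the training segment.
#' @return scalar `gamma` (0 with a warning when the parent segment has zero
#'   energy).
#' @export
estimate_gamma <- function(e_c, e_r, n0 = 1L, N = length(e_r)) {
  idx <- n0:N
  er <- as.numeric(e_r[idx]); ec <- as.numeric(e_c[idx])
  den <- sum(er * er)
  if (den == 0) {
    warning("zero-energy reference segment; gamma set to 0")
    return(0)
  }
  sum(ec * er) / den
}

#' Residual energy
#'
#' Sum of squared samples of a decorrelated series; coding length grows with
#' this energy, so it drives both the gamma optimum and the spanning-tree
#' edge weights.
#'
#' @param e_tilde decorrelated series.
#' @return scalar energy.
#' @export
energy <- function(e_tilde) sum(as.numeric(e_tilde)^2)

GAMMA_FRAC_BITS <- 14L   # Q1.14: 1 sign, 1 integer, 14 fraction bits

quantize_gamma <- function(gamma) {
  q <- round(gamma * 2^GAMMA_FRAC_BITS)
  as.integer(max(-2^15, min(2^15 - 1, q)))
}

# round half away from zero, mirrored exactly in encoder and decoder
round_haz <- function(x) sign(x) * floor(abs(x) + 0.5)

spatial_predict <- function(gamma_q, e_r) {
  as.integer(round_haz(gamma_q * as.numeric(e_r) / 2^GAMMA_FRAC_BITS))
}

#' Train the channel tree for cross-channel compression
#'
#' Temporally decorrelates every channel, then builds a complete graph whose
#' edge weight between two channels is the per-sample residual energy of one
#' predicted from the other at the optimal gamma (symmetrized by taking the
#' smaller direction), and extracts a minimum spanning tree rooted at the
#' smallest channel index (ties broken toward lower indices, so training is
#' deterministic).  Each child's gamma is quantized to Q1.14 fixed point.
#'
#' @param rec a [new_recording()] (2..8 channels selected).
#' @param channels channel ids to include (default: all).
#' @param n0 first sample of the training segment.
#' @param N last sample of the training segment; segment lengths of
#'   1000-2000 samples are enough for gamma to stabilize.
#' @return a `channel_tree`: list with `root`, `parent` (named integer map
#'   child -> parent), `gamma_q` (named Q1.14 integers per child), `order`
#'   (topological channel order), `n0`, `N`, `channels`.
#' @export
train_channel_tree <- function(rec, channels = rec$channel_ids,
                               n0 = 1L, N = NULL) {
  C <- length(channels)
  if (C < 2) stopf("channel-tree training requires at least 2 channels")
  if (C > 8) stopf("the cross-channel engine groups at most 8 channels")
  n <- ncol(rec$samples)
  if (is.null(N)) N <- min(n, n0 + 1999L)
  if (N > n || n0 < 1 || n0 >= N) stopf("invalid training segment [n0, N]")
  e <- lapply(channels, function(ch) temporal_decorrelate(rec_channel(rec, ch)))
  names(e) <- as.character(channels)
  # directed residual energies per sample after optimal gamma
  resid_energy <- function(ci, pi) {
    g <- suppressWarnings(estimate_gamma(e[[ci]], e[[pi]], n0, N))
    idx <- n0:N
    energy(as.numeric(e[[ci]][idx]) - g * as.numeric(e[[pi]][idx])) /
      length(idx)
  }
  W <- matrix(Inf, C, C)
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    w <- min(resid_energy(i, j), resid_energy(j, i))
    W[i, j] <- w; W[j, i] <- w
  }
  # Prim's MST from the smallest channel index; deterministic tie-breaks
  root_i <- which.min(channels)
  in_tree <- rep(FALSE, C); in_tree[root_i] <- TRUE
  parent <- rep(NA_integer_, C)
  for (step in seq_len(C - 1)) {
    best <- c(Inf, NA, NA)
    for (u in order(channels)[in_tree[order(channels)]]) {
      for (v in order(channels)) {
        if (in_tree[v]) next
        if (W[u, v] < best[1]) best <- c(W[u, v], u, v)
      }
    }
    u <- best[2]; v <- best[3]
    parent[v] <- u
    in_tree[v] <- TRUE
  }
  # topological order: root first, then children in discovery order
  kids <- function(i) which(parent == i)
  ord <- root_i
  frontier <- root_i
  while (length(frontier)) {
    nxt <- unlist(lapply(frontier, kids))
    ord <- c(ord, nxt)
    frontier <- nxt
  }
  child_i <- ord[-1]
  gq <- vapply(child_i, function(ci) {
    quantize_gamma(suppressWarnings(
      estimate_gamma(e[[ci]], e[[parent[ci]]], n0, N)))
  }, integer(1))
  structure(list(root = channels[root_i],
                 parent = stats::setNames(channels[parent[child_i]],
                                          channels[child_i]),
                 gamma_q = stats::setNames(gq, channels[child_i]),
                 order = channels[ord],
                 n0 = as.integer(n0), N = as.integer(N),
                 channels = as.integer(channels)),
            class = "channel_tree")
}

#' @export
print.channel_tree <- function(x, ...) {
  cat(sprintf("<channel_tree> root %d, %d channel(s)\n", x$root,
              length(x$channels)))
  for (ch in names(x$parent))
    cat(sprintf("  %s <- %d (gamma = %.4f)\n", ch, x$parent[ch],
                x$gamma_q[ch] / 2^GAMMA_FRAC_BITS))
  invisible(x)
}

#' Cross-channel compression of an LFP group
#'
#' The root channel's temporal residuals are coded directly; every child, in
#' topological order, is coded as
#' `e_child[n] - round(gamma_q * e_parent[n])` with the quantized gamma and
#' round-half-away-from-zero, so the decoder (which reproduces the identical
#' integer arithmetic from the parent's decoded residuals) inverts exactly.
#' All residuals are zigzag-mapped and Golomb-coded with block adaptation.
#'
#' @param rec a [new_recording()] holding the aligned group.
#' @param tree a [train_channel_tree()] result for these channels.
#' @param k_init initial Rice parameter.
#' @return a `cce_bitstream`: list with `tree`, per-channel payload `bits`,
#'   `n_samples`, `payload_nbits`.
#' @export
cce_compress <- function(rec, tree, k_init = 3L) {
  stopifnot(inherits(tree, "channel_tree"))
  if (!all(tree$channels %in% rec$channel_ids))
    stopf("tree channels are not all present in the recording")
  n <- ncol(rec$samples)
  e <- lapply(tree$channels, function(ch)
    temporal_decorrelate(rec_channel(rec, ch)))
  names(e) <- as.character(tree$channels)
  bits <- vector("list", length(tree$order))
  names(bits) <- as.character(tree$order)
  for (ch in tree$order) {
    key <- as.character(ch)
    et <- if (ch == tree$root) e[[key]]
          else e[[key]] - spatial_predict(tree$gamma_q[key],
                                          e[[as.character(tree$parent[key])]])
    bits[[key]] <- rice_adaptive_encode(map_to_nonneg(et), k_init = k_init)
  }
  structure(list(tree = tree, bits = bits, n_samples = n,
                 k_init = as.integer(k_init),
                 fs = rec$fs, bit_depth = rec$bit_depth,
                 payload_nbits = sum(lengths(bits))),
            class = "cce_bitstream")
}

#' @rdname cce_compress
#' @param bs a `cce_bitstream`.
#' @return `cce_decompress`: a [new_recording()] identical to the compressed
#'   group (lossless).
#' @export
cce_decompress <- function(bs) {
  stopifnot(inherits(bs, "cce_bitstream"))
  tree <- bs$tree
  n <- bs$n_samples
  e <- list()
  for (ch in tree$order) {
    key <- as.character(ch)
    et <- map_from_nonneg(
      rice_adaptive_decode(bs$bits[[key]], n, k_init = bs$k_init)$values)
    e[[key]] <- if (ch == tree$root) et
                else et + spatial_predict(tree$gamma_q[key],
                                          e[[as.character(tree$parent[key])]])
  }
  samples <- do.call(rbind, lapply(tree$channels, function(ch)
    temporal_recorrelate(e[[as.character(ch)]])))
  new_recording(samples, fs = bs$fs, bit_depth = bs$bit_depth,
                channel_ids = tree$channels)
}
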