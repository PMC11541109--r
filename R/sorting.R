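PCA_MAX_FEATURES <- 10L
AF_MAX_FEATURES <- 7L
KMEANS_MAX_K <- 8L
ALIGN_INDEX <- 20L    # sample at which the maximum-slope point is placed

#' Align a spike waveform at its maximum-slope sample
#'
#' Shifts the 64-sample waveform so that the sample of maximum first
#' difference sits at index 20 (ties broken to the earliest sample);
#' out-of-window samples are zero-padded.  Alignment removes detection
#' jitter before feature extraction.
#'
#' @param waveform 64-sample numeric/integer vector, or an `n x 64` matrix
#'   (rows aligned independently).
#' @return aligned waveform(s), same shape as the input.
#' @export
align_max_slope <- function(waveform) {
  if (is.matrix(waveform))
    return(t(apply(waveform, 1, align_max_slope)))
  if (length(waveform) != 64) stopf("waveform must have exactly 64 samples")
  d <- diff(as.numeric(waveform))
  peak <- which.max(d)            # which.max takes the earliest tie
  shift <- ALIGN_INDEX - peak
  out <- numeric(64)
  src <- seq_len(64) - shift
  ok <- src >= 1 & src <= 64
  out[ok] <- waveform[src[ok]]
  out
}

#' PCA feature training
#'
#' Principal axes of the mean-centered aligned spike matrix, with a
#' deterministic sign convention (the largest-magnitude loading of each axis
#' is positive).  At most 10 features.
#'
#' @param S `n_spikes x 64` aligned spike matrix.
#' @param n_features number of components (<= 10).
#' @return a `feature_matrix`: list with `projection`
#'   (`n_features x 64`, orthonormal rows), `center` (64-vector), and
#'   `kind = "pca"`.
#' @export
pca_train <- function(S, n_features) {
  if (n_features > PCA_MAX_FEATURES)
    stopf("PCA supports at most %d features", PCA_MAX_FEATURES)
  if (nrow(S) <= n_features)
    stopf("need more spikes than features")
  p <- prcomp(S, center = TRUE, scale. = FALSE)
  proj <- t(p$rotation[, seq_len(n_features), drop = FALSE])
  # sign convention: largest |loading| positive per row
  for (i in seq_len(nrow(proj))) {
    j <- which.max(abs(proj[i, ]))
    if (proj[i, j] < 0) proj[i, ] <- -proj[i, ]
  }
  structure(list(projection = proj, center = p$center, kind = "pca"),
            class = "feature_matrix")
}

#' Discriminative-sample ("adaptive filter") feature training
#'
#' Selects the sample positions that best separate the provisional classes:
#' positions are ranked by the between-class to within-class variance ratio
#' (F-ratio) of the aligned spikes, and the top `n_features` distinct
#' positions become rows of a sparse 0/1 projection, so projection reduces
#' to indexing the selected samples.  At most 7 features.
#'
#' @param S `n_spikes x 64` aligned spike matrix.
#' @param labels provisional class labels, length `n_spikes`.
#' @param n_features number of positions to select (<= 7).
#' @return a `feature_matrix` with sparse `projection`, `center = 0`,
#'   `kind = "af"`, and the chosen `positions`.
#' @export
af_train <- function(S, labels, n_features) {
  if (n_features > AF_MAX_FEATURES)
    stopf("AF supports at most %d features", AF_MAX_FEATURES)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("AF training needs at least 2 classes")
  grand <- colMeans(S)
  between <- numeric(ncol(S)); within <- numeric(ncol(S))
  for (g in levels(labels)) {
    Sg <- S[labels == g, , drop = FALSE]
    mg <- colMeans(Sg)
    between <- between + nrow(Sg) * (mg - grand)^2
    within <- within + colSums(sweep(Sg, 2, mg)^2)
  }
  fratio <- between / pmax(within, .Machine$double.eps)
  positions <- order(-fratio)[seq_len(n_features)]
  proj <- matrix(0, n_features, ncol(S))
  proj[cbind(seq_len(n_features), positions)] <- 1
  structure(list(projection = proj, center = rep(0, ncol(S)), kind = "af",
                 positions = positions),
            class = "feature_matrix")
}

#' Blocked projection of spikes into feature space
#'
#' Matrix product of the (centered) spike matrix with the transposed
#' projection, evaluated block row-by-column the way a hardware
#' multiply-accumulate engine walks the operands; the result is independent
#' of the block size and equals the plain matrix product.
#'
#' @param S `n_spikes x 64` spike matrix.
#' @param F a `feature_matrix`.
#' @param block block edge length for the tiled evaluation.
#' @return `n_spikes x n_features` feature matrix.
#' @export
mac_project <- function(S, F, block = 8L) {
  if (!is.matrix(S)) S <- matrix(S, nrow = 1)
  P <- F$projection
  if (ncol(S) != ncol(P)) stopf("spike and projection dimensions disagree")
  Sc <- sweep(S, 2, F$center)
  out <- matrix(0, nrow(S), nrow(P))
  for (k0 in seq(1, ncol(Sc), by = block)) {
    kk <- k0:min(k0 + block - 1L, ncol(Sc))
    out <- out + Sc[, kk, drop = FALSE] %*% t(P[, kk, drop = FALSE])
  }
  out
}

# k-means++ seeding: spread initial centers, deterministic given the RNG state
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) for (i in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[i, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[i, ])^2))
  }
  centers
}

mean_silhouette <- function(D, cl) {
  s <- cluster::silhouette(cl, dist = D)
  mean(s[, "sil_width"])
}

#' K-means clustering of spike features with automatic k
#'
#' k-means++ seeding followed by Lloyd iterations; the number of clusters is
#' chosen over `k = 2..k_max` (capped at 8) by the mean silhouette width.
#' Per-cluster covariances are estimated and ridge-regularized
#' (`1e-3 * trace / d` on the diagonal) for Mahalanobis classification.
#' Deterministic for a fixed seed.
#'
#' @param features `n x d` feature matrix.
#' @param k number of clusters; `NULL` (default) selects by silhouette.
#' @param k_max largest k considered (<= 8).
#' @param seed RNG seed for the seeding step.
#' @param n_start number of k-means++ restarts; the fit with the lowest
#'   total within-cluster sum of squares is kept.
#' @param iter_max Lloyd iteration cap.
#' @return a `cluster_model`: list with `means` (`k x d`), `covariances`
#'   (list of `d x d`), `k`, `sizes`.
#' @export
kmeans_train <- function(features, k = NULL, k_max = KMEANS_MAX_K, seed = 1L,
                         n_start = 5L, iter_max = 100L) {
  if (k_max > KMEANS_MAX_K)
    stopf("the number of clusters is capped at %d", KMEANS_MAX_K)
  X <- as.matrix(features)
  n <- nrow(X)
  if (!is.null(k) && n < k) stopf("fewer spikes than clusters")
  with_seed(seed, {
    fit_k <- function(kk) {
      fits <- lapply(seq_len(n_start), function(r) {
        init <- kmeanspp_init(X, kk)
        suppressWarnings(kmeans(X, centers = init, iter.max = iter_max,
                                algorithm = "Lloyd"))
      })
      fits[[which.min(vapply(fits, `[[`, numeric(1), "tot.withinss"))]]
    }
    if (is.null(k)) {
      ks <- 2:min(k_max, n - 1)
      if (length(ks) == 0 || min(ks) > max(ks)) ks <- 1L
      D <- stats::dist(X)
      fits <- lapply(ks, fit_k)
      sil <- vapply(seq_along(ks), function(i) {
        if (ks[i] < 2) return(-Inf)
        mean_silhouette(D, fits[[i]]$cluster)
      }, numeric(1))
      best <- which.max(sil)
      fit <- fits[[best]]
    } else {
      fit <- fit_k(k)
    }
    d <- ncol(X)
    covs <- lapply(seq_len(nrow(fit$centers)), function(i) {
      Xi <- X[fit$cluster == i, , drop = FALSE]
      Sg <- if (nrow(Xi) > 1) cov(Xi) else matrix(0, d, d)
      ridge <- max(1e-3 * sum(diag(Sg)) / d, 1e-9)
      Sg + diag(ridge, d)
    })
    structure(list(means = fit$centers, covariances = covs,
                   k = nrow(fit$centers), sizes = fit$size,
                   cluster = fit$cluster),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, sizes: %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Nearest-cluster classification
#'
#' Assigns each feature vector to the cluster minimizing the Euclidean or
#' Mahalanobis distance `(f - mu)' Sigma^-1 (f - mu)`; ties go to the lowest
#' cluster id.
#'
#' @param features vector or `n x d` matrix of feature vectors.
#' @param model a [kmeans_train()] model.
#' @param metric `"euclidean"` or `"mahalanobis"`.
#' @return integer cluster ids.
#' @export
classify <- function(features, model, metric = c("euclidean", "mahalanobis")) {
  metric <- match.arg(metric)
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  D <- vapply(seq_len(model$k), function(i) {
    if (metric == "euclidean")
      rowSums(sweep(X, 2, model$means[i, ])^2)
    else
      mahalanobis(X, model$means[i, ], model$covariances[[i]])
  }, numeric(nrow(X)))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)
  max.col(-D, ties.method = "first")
}

#' Sorting accuracy under optimal cluster-to-class matching
#'
#' Percentage of spikes correctly labeled under the best one-to-one
#' assignment between predicted clusters and ground-truth classes (optimal
#' bipartite matching on the confusion matrix, exhaustive over permutations,
#' which is exact for up to 8 clusters).
#'
#' @param predicted predicted cluster labels.
#' @param truth ground-truth class labels (same length).
#' @return accuracy percentage in `[0, 100]`.
#' @export
sorting_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stopf("label lengths differ")
  if (length(truth) == 0) return(NA_real_)
  cm <- table(factor(predicted), factor(truth))
  m <- max(dim(cm))
  M <- matrix(0, m, m)
  M[seq_len(nrow(cm)), seq_len(ncol(cm))] <- cm
  best <- 0
  perm_rec <- function(used, i, acc) {
    if (acc + sum(apply(M[, setdiff(seq_len(m), used), drop = FALSE], 2, max)) <= best)
      return()
    if (i > m) { best <<- max(best, acc); return() }
    for (j in setdiff(seq_len(m), used))
      perm_rec(c(used, j), i + 1, acc + M[i, j])
  }
  perm_rec(integer(0), 1, 0)
  100 * best / length(truth)
}

#' End-to-end spike sorting of a recording channel
#'
#' Detects spikes, aligns them at maximum slope, extracts features (PCA or
#' discriminative samples), clusters with [kmeans_train()], and classifies
#' every spike.
#'
#' @param rec a [new_recording()].
#' @param channel channel id.
#' @param n_features feature count (<= 10 for PCA, <= 7 for AF).
#' @param kind `"pca"` or `"af"`.
#' @param metric distance metric for assignment.
#' @param k fixed cluster count, or `NULL` for silhouette selection.
#' @param seed RNG seed.
#' @param config detector configuration.
#' @return list with `events`, `features`, `feature_matrix`, `model`,
#'   `labels`.
#' @export
sort_spikes <- function(rec, channel, n_features = 3, kind = c("pca", "af"),
                        metric = c("euclidean", "mahalanobis"), k = NULL,
                        seed = 1L, config = ate_config()) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  ev <- detect_spikes(rec, channel, config)
  if (nrow(ev$events) < 2) stopf("not enough detected spikes to sort")
  A <- align_max_slope(ev$waveforms)
  if (kind == "pca") {
    Fm <- pca_train(A, n_features)
    feats <- mac_project(A, Fm)
    model <- kmeans_train(feats, k = k, seed = seed)
  } else {
    # provisional labels from a PCA + k-means pass drive the AF selection
    Fp <- pca_train(A, min(3L, nrow(A) - 1L))
    prov <- kmeans_train(mac_project(A, Fp), k = k, seed = seed)
    Fm <- af_train(A, prov$cluster, n_features)
    feats <- mac_project(A, Fm)
    model <- kmeans_train(feats, k = k, seed = seed)
  }
  labels <- classify(feats, model, metric)
  list(events = ev, features = feats, feature_matrix = Fm, model = model,
       labels = labels)
}
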