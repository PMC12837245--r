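# K-means frame-clustering features: each segment is sliced into short frames,
# frames are summarized by simple statistics, and Lloyd's algorithm with the
# squared-Euclidean dissimilarity clusters them; the sorted centroids,
# occupancy fractions and inertia describe the segment.

#' Squared Euclidean distance
#'
#' The dissimilarity used by the frame clustering:
#' `sum((p - q)^2) = ||p - q||^2`.
#'
#' @param p,q numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
squared_euclidean <- function(p, q) {
  if (length(p) != length(q)) stopf("points must have equal dimension")
  sum((p - q)^2)
}

# Seeded Lloyd clustering with deterministic centroid ordering (by first
# coordinate, then subsequent ones). Restarts guard against empty clusters.
fit_kmeans <- function(points, K, seed = 1L, nstart = 5L) {
  points <- as.matrix(points)
  if (nrow(points) < K) stopf("fewer points (%d) than clusters (%d)", nrow(points), K)
  km <- with_local_seed(seed, suppressWarnings(
    stats::kmeans(points, centers = K, algorithm = "Lloyd",
                  iter.max = 100L, nstart = nstart)))
  ord <- do.call(order, as.data.frame(km$centers))
  list(centers = km$centers[ord, , drop = FALSE],
       occupancy = as.vector(table(factor(km$cluster, levels = seq_len(K)))[ord]) /
         nrow(points),
       inertia = km$tot.withinss)
}

frame_summaries <- function(x, frame_len) {
  k <- length(x) %/% frame_len
  fr <- matrix(x[seq_len(k * frame_len)], nrow = k, byrow = TRUE)
  cbind(mean = rowMeans(fr),
        sd = apply(fr, 1, stats::sd),
        energy = rowMeans(fr^2),
        p2p = apply(fr, 1, function(v) max(v) - min(v)))
}

#' K-means frame-clustering features
#'
#' Each segment is sliced into non-overlapping frames of `frame_seconds`;
#' frames are summarized by (mean, SD, energy, peak-to-peak); Lloyd's
#' algorithm with squared-Euclidean distance clusters the frame summaries.
#' Per-segment features are the sorted centroid coordinates, the matching
#' cluster occupancy fractions and the total within-cluster inertia
#' (`4K + K + 1` features).
#'
#' @param segments a `segment_set`.
#' @param K number of clusters (>= 2).
#' @param frame_seconds frame length in seconds.
#' @param seed RNG seed for the clustering initialization.
#' @return A [feature_table()].
#' @export
kmeans_features <- function(segments, K = 4L, frame_seconds = 2, seed = 1L) {
  if (!is_count(K, 2L)) stopf("K must be a count >= 2")
  frame_len <- max(2L, round(frame_seconds * segments$fs))
  n_frames <- ncol(segments$segments) %/% frame_len
  if (n_frames < K) {
    stopf("segments yield %d frames, fewer than K = %d", n_frames, K)
  }
  feats <- t(vapply(seq_len(nrow(segments$segments)), function(i) {
    fs <- frame_summaries(segments$segments[i, ], frame_len)
    km <- fit_kmeans(fs, K, derive_seed(seed, i))
    c(as.vector(t(km$centers)), km$occupancy, km$inertia)
  }, numeric(4L * K + K + 1L)))
  nm <- c(as.vector(t(outer(paste0("c", seq_len(K)),
                            c("mean", "sd", "energy", "p2p"), paste, sep = "_"))),
          paste0("occ", seq_len(K)), "inertia")
  feats[!is.finite(feats)] <- 0
  feature_table(feats, segments$labels, nm,
                provenance = list(extractor = "kmeans", K = K,
                                  frame_seconds = frame_seconds))
}
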