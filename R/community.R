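#' Configuration for the consensus community matrix
#'
#' Parameters of the repeated k-means consensus. Regions are clustered as
#' points in T-dimensional time space under squared Euclidean distance; `L`
#' independently initialized runs are averaged into a co-assignment
#' probability matrix. A deliberately large `k` keeps the matrix sparse so
#' that only strongly cooperative regions share a cluster.
#'
#' @param k number of clusters (default 30).
#' @param L number of clustering trials averaged (default 500).
#' @param max_iter iteration cap per trial (default 300).
#' @param seed master RNG seed; trial seeds are derived from it by a counter.
#' @param standardize_rows z-score each region's series before clustering
#'   (default TRUE), making the consensus invariant to per-region amplitude.
#' @param cluster_scope `"all_regions"` (default) clusters every atlas region;
#'   `"cortical_only"` restricts to cortical rows (requires an atlas at call
#'   time).
#' @return a `community_config` list.
#' @export
community_config <- function(k = 30, L = 500, max_iter = 300, seed = 1L,
                             standardize_rows = TRUE,
                             cluster_scope = c("all_regions", "cortical_only")) {
  cluster_scope <- match.arg(cluster_scope)
  stopifnot(k >= 2, L >= 1, max_iter >= 1)
  structure(list(k = as.integer(k), L = as.integer(L),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 standardize_rows = isTRUE(standardize_rows),
                 cluster_scope = cluster_scope),
            class = "community_config")
}

#' One k-means partition of points
#'
#' Lloyd iteration with the exact deterministic conventions used throughout
#' the package: centroids are initialized by sampling `k` distinct data points
#' without replacement; each point joins its nearest centroid under squared
#' Euclidean distance with ties broken by the lowest centroid index; a cluster
#' emptied during assignment is re-seeded with the point currently farthest
#' from its own centroid; iteration stops at an exact label fixed point or at
#' `max_iter`.
#'
#' @param points N x T numeric matrix (rows are the points).
#' @param k number of clusters, `1 <= k <= N`.
#' @param seed RNG seed for the initialization draw; `NULL` uses the current
#'   RNG state.
#' @param max_iter iteration cap.
#' @return integer vector of cluster labels in `1..k`. Identical rows always
#'   receive identical labels.
#' @export
kmeans_partition <- function(points, k, seed = NULL, max_iter = 300L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (any(!is.finite(points))) stop("non-finite values in points")
  if (k < 1 || k > n) stop("k must be between 1 and the number of points")
  init <- if (is.null(seed)) sample.int(n, k) else
    withr::with_seed(seed, sample.int(n, k))
  centroids <- points[init, , drop = FALSE]
  pp <- rowSums(points^2)
  labels <- rep.int(0L, n)
  for (iter in seq_len(max_iter)) {
    ## squared distances point->centroid; max.col(ties "first") = lowest index
    D <- outer(pp, rowSums(centroids^2), "+") - 2 * points %*% t(centroids)
    new_labels <- max.col(-D, ties.method = "first")
    dmin <- D[cbind(seq_len(n), new_labels)]
    empty <- setdiff(seq_len(k), unique(new_labels))
    guard <- 0L
    while (length(empty) > 0 && guard < k) {
      far <- which.max(dmin)
      centroids[empty[1], ] <- points[far, ]
      D <- outer(pp, rowSums(centroids^2), "+") - 2 * points %*% t(centroids)
      new_labels <- max.col(-D, ties.method = "first")
      dmin <- D[cbind(seq_len(n), new_labels)]
      empty <- setdiff(seq_len(k), unique(new_labels))
      guard <- guard + 1L
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (c in unique(labels))
      centroids[c, ] <- colMeans(points[labels == c, , drop = FALSE])
  }
  labels
}

#' Co-assignment matrix of one partition
#'
#' @param labels integer label vector.
#' @return binary N x N matrix with 1 where two points share a label; a
#'   symmetric, transitive equivalence-relation matrix with unit diagonal.
#' @export
coassignment <- function(labels) {
  m <- outer(labels, labels, "==")
  storage.mode(m) <- "double"
  m
}

#' Consensus community matrix of one subject
#'
#' Averages the co-assignment matrices of `L` independently seeded
#' [kmeans_partition()] runs on the region-by-time matrix, yielding the
#' empirical probability that each pair of regions shares a functional
#' cluster. Deterministic given (`seed`, `k`, `L`).
#'
#' @param ts a [regional_ts()] or a plain P x T matrix.
#' @param cfg a [community_config()].
#' @param atlas optional `region_atlas`; required for
#'   `cluster_scope = "cortical_only"`.
#' @return a [community_matrix()] over the clustered regions, with the
#'   configuration recorded in `$config`.
#' @export
consensus_community_matrix <- function(ts, cfg = community_config(),
                                       atlas = NULL) {
  vals <- if (inherits(ts, "regional_ts")) ts$values else as.matrix(ts)
  if (cfg$cluster_scope == "cortical_only") {
    if (is.null(atlas)) stop("cortical_only scope requires an atlas")
    vals <- vals[which(atlas$cortical), , drop = FALSE]
  }
  p <- nrow(vals)
  if (p < cfg$k) stop("k (", cfg$k, ") exceeds number of regions (", p, ")")
  if (cfg$standardize_rows) vals <- t(apply(vals, 1, zscore_pop))
  acc <- matrix(0, p, p)
  for (l in seq_len(cfg$L)) {
    lab <- kmeans_partition(vals, cfg$k, seed = derive_seed(cfg$seed, l),
                            max_iter = cfg$max_iter)
    acc <- acc + coassignment(lab)
  }
  K <- acc / cfg$L
  diag(K) <- 1
  if (!is.null(rownames(vals))) dimnames(K) <- list(rownames(vals), rownames(vals))
  community_matrix(K, config = unclass(cfg))
}

#' Stability of the consensus matrix across k
#'
#' Recomputes the consensus matrix over a grid of cluster counts and reports
#' the Frobenius norm of the difference from a reference-k matrix. At
#' `k = reference_k` the norm is computed between two independently seeded
#' runs, which measures the pure Monte-Carlo sampling floor of the consensus.
#'
#' @param ts a [regional_ts()] or P x T matrix.
#' @param k_values integer grid of cluster counts.
#' @param reference_k the reference cluster count.
#' @param cfg a [community_config()] (its `k` field is ignored).
#' @param atlas optional atlas for cortical scope.
#' @return data.frame with columns `k` and `frobenius`.
#' @export
stability_sweep <- function(ts, k_values, reference_k,
                            cfg = community_config(), atlas = NULL) {
  mk <- function(k, seed_offset) {
    c2 <- cfg; c2$k <- as.integer(k)
    c2$seed <- derive_seed(cfg$seed, seed_offset)
    consensus_community_matrix(ts, c2, atlas)$K
  }
  Kref <- mk(reference_k, 0L)
  fro <- vapply(seq_along(k_values), function(idx) {
    k <- k_values[idx]
    Kk <- mk(k, idx)  # fresh seed even when k == reference_k
    norm(Kk - Kref, type = "F")
  }, numeric(1))
  data.frame(k = as.integer(k_values), frobenius = fro)
}
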