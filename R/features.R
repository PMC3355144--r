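#' Vectorize a community matrix into edge features
#'
#' Extracts the strict upper triangle of the matrix restricted to the given
#' regions, in canonical row-major order. For the default 90 cortical regions
#' this is the 90*89/2 = 4005-dimensional edge vector.
#'
#' @param K a [community_matrix()] or plain symmetric matrix.
#' @param include 1-based indices of regions to keep (default: all).
#' @return numeric edge vector of length `p*(p-1)/2`.
#' @export
vectorize_edges <- function(K, include = NULL) {
  Km <- if (inherits(K, "community_matrix")) K$K else as.matrix(K)
  if (!is.null(include)) {
    if (length(include) == 0) stop("include must be nonempty")
    Km <- Km[include, include, drop = FALSE]
  }
  vectorize_upper(Km)
}

#' Edge feature table for a cohort
#'
#' @param values subjects x E numeric matrix of edge features.
#' @param index data.frame `(i, j)` of 1-based region indices defining the
#'   column order (see [edge_index()]).
#' @param source `"community"` or `"crosscorrelation"`.
#' @param region_names optional names of the included regions.
#' @return object of class `edge_features`.
#' @export
edge_feature_table <- function(values, index,
                               source = c("community", "crosscorrelation"),
                               region_names = NULL) {
  source <- match.arg(source)
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(index))
  structure(list(values = values, edge_index = index, source = source,
                 region_names = region_names),
            class = "edge_features")
}

#' Cross-correlation edge features of one subject
#'
#' Pearson correlations between the raw regional series, vectorized in the
#' same canonical edge order as the community features; the conventional
#' functional-connectivity baseline.
#'
#' @param ts a [regional_ts()] or P x T matrix.
#' @param include 1-based region indices to keep.
#' @return numeric edge vector.
#' @export
crosscorrelation_edges <- function(ts, include = NULL) {
  vals <- if (inherits(ts, "regional_ts")) ts$values else as.matrix(ts)
  if (!is.null(include)) vals <- vals[include, , drop = FALSE]
  vectorize_upper(stats::cor(t(vals)))
}

#' Resampled sparse-regression edge selection
#'
#' Ranks edges by their aggregated L1-regression coefficient magnitude over
#' repeated class-stratified subject subsamples. For each of `B` subsamples
#' (fraction `frac` per class, without replacement) an L1-penalized linear
#' regression of the +1/-1 labels on the column-standardized features is
#' fitted with the penalty chosen by internal cross-validation; coefficient
#' magnitudes (or selection indicators, with `aggregate = "freq"`) are then
#' averaged across subsamples. Aggregating over subsamples preserves groups
#' of correlated discriminative edges that a single lasso fit would thin out.
#'
#' @param features an `edge_features` table or plain subjects x E matrix.
#' @param labels +1/-1 vector, one per subject (both classes required).
#' @param n_keep number of edges to select (default 400).
#' @param B number of resamples (default 100).
#' @param frac subsample fraction per class (default 0.8).
#' @param seed RNG seed.
#' @param aggregate `"mean_abs"` (default) averages `|coefficient|`;
#'   `"freq"` averages the nonzero indicator.
#' @param nfolds folds for the internal penalty cross-validation (default 5).
#' @return object of class `sparse_selection`: `coef` (aggregated magnitudes),
#'   `ranking` (edge columns sorted by decreasing `coef`, ties broken by
#'   canonical edge order), `selected` (first `n_keep` of the ranking),
#'   `n_selected`, `resamples`, `subsample_fraction`, `lambda_rule`.
#' @export
sparse_select <- function(features, labels, n_keep = 400, B = 100,
                          frac = 0.8, seed = 1L,
                          aggregate = c("mean_abs", "freq"), nfolds = 5) {
  aggregate <- match.arg(aggregate)
  x <- if (inherits(features, "edge_features")) features$values else
    as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(x); E <- ncol(x)
  if (length(labels) != n) stop("labels length must match feature rows")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (n_keep > E) stop("n_keep exceeds number of edges")
  pos <- which(labels == 1L); neg <- which(labels == -1L)
  npos <- max(1L, floor(frac * length(pos)))
  nneg <- max(1L, floor(frac * length(neg)))
  acc <- numeric(E)
  for (b in seq_len(B)) {
    idx <- NULL
    for (try in 1:10) {
      idx <- withr::with_seed(derive_seed(seed, b * 131L + try), {
        c(sample(pos, npos), sample(neg, nneg))
      })
      if (length(unique(labels[idx])) == 2) break
      idx <- NULL
    }
    if (is.null(idx)) stop("could not draw a two-class resample")
    nf <- max(3L, min(nfolds, length(idx)))
    ## small fixtures trigger glmnet's "< 3 observations per fold" notice
    cv <- suppressWarnings(withr::with_seed(derive_seed(seed, b * 131L), {
      glmnet::cv.glmnet(x[idx, , drop = FALSE], labels[idx],
                        family = "gaussian", alpha = 1,
                        standardize = TRUE, nfolds = nf)
    }))
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    ## glmnet reports beta on the original feature scale; rescale to the
    ## standardized scale so the ranking is invariant to column units
    sdv <- apply(x[idx, , drop = FALSE], 2, stats::sd)
    acc <- acc + if (aggregate == "mean_abs") abs(beta) * sdv else
      as.numeric(beta != 0)
  }
  coef <- acc / B
  ranking <- order(coef, decreasing = TRUE)  # stable: ties keep canonical order
  structure(list(coef = coef, ranking = ranking,
                 selected = ranking[seq_len(n_keep)],
                 n_selected = as.integer(n_keep), resamples = as.integer(B),
                 subsample_fraction = frac,
                 lambda_rule = sprintf("lambda.min by %d-fold CV", nfolds),
                 aggregate = aggregate),
            class = "sparse_selection")
}

#' @export
print.sparse_selection <- function(x, ...) {
  cat(sprintf("<sparse_selection> %d of %d edges (B=%d, frac=%.2f, %s)\n",
              x$n_selected, length(x$coef), x$resamples,
              x$subsample_fraction, x$aggregate))
  invisible(x)
}

#' Rank-sum group test per edge
#'
#' Two-sided Wilcoxon rank-sum test per edge between the two groups, flagged
#' at a Bonferroni-corrected level `alpha / m`. `m` is the effective number of
#' comparisons; with sparse community matrices a sensible choice is the
#' number of nonzero entries of the grand-mean matrix (see
#' [nonzero_edge_count()]). The distribution of community-matrix edges is far
#' from Gaussian, hence a rank test rather than a t-test.
#'
#' @param features an `edge_features` table or subjects x E matrix.
#' @param labels +1/-1 vector (>= 2 subjects per class).
#' @param alpha family-wise level (default 0.05).
#' @param m effective number of comparisons.
#' @return data.frame with columns `edge`, `i`, `j` (if available), `p`,
#'   `significant`; attribute `threshold` = `alpha/m`. Fully tied edges get
#'   p = 1.
#' @export
ranksum_edges <- function(features, labels, alpha = 0.05, m) {
  x <- if (inherits(features, "edge_features")) features$values else
    as.matrix(features)
  idx <- if (inherits(features, "edge_features")) features$edge_index else NULL
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2 || sum(labels == -1L) < 2)
    stop("need at least 2 subjects per class")
  thr <- alpha / m
  p <- apply(x, 2, function(col) {
    a <- col[labels == 1L]; b <- col[labels == -1L]
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  })
  out <- data.frame(edge = seq_along(p),
                    i = if (is.null(idx)) NA_integer_ else idx$i,
                    j = if (is.null(idx)) NA_integer_ else idx$j,
                    p = unname(p), significant = unname(p < thr))
  attr(out, "threshold") <- thr
  out
}

#' Count nonzero entries of a mean community matrix
#'
#' Number of strict-upper-triangle entries exceeding `threshold`; used as the
#' effective comparison count for the Bonferroni correction of the edge
#' rank-sum tests.
#'
#' @param K a [community_matrix()] or symmetric matrix (typically a group or
#'   grand mean).
#' @param threshold probability threshold in `[0, 1)` (default 0.05).
#' @return integer count.
#' @export
nonzero_edge_count <- function(K, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold < 1)
  sum(vectorize_edges(K) > threshold)
}

#' Group statistics of an asymmetry index
#'
#' Per homolog pair: group means of the index in controls (+1) and patients
#' (-1), their patient/control ratio, and the two-sided two-sample t-test
#' p-value. Pairs with undefined values (NA) in a subject are dropped from
#' that pair's statistics.
#'
#' @param values subjects x pairs matrix of rho or d.
#' @param labels +1/-1 vector.
#' @return data.frame with columns `pair`, `mean_H`, `mean_P`, `ratio`, `p`;
#'   `ratio` is NA when `mean_H` is 0.
#' @export
asymmetry_group_stats <- function(values, labels) {
  values <- as.matrix(values)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  h <- labels == 1L; pt <- labels == -1L
  out <- lapply(seq_len(ncol(values)), function(q) {
    vh <- values[h, q]; vp <- values[pt, q]
    vh <- vh[!is.na(vh)]; vp <- vp[!is.na(vp)]
    mh <- mean(vh); mp <- mean(vp)
    data.frame(pair = colnames(values)[q] %||% as.character(q),
               mean_H = mh, mean_P = mp,
               ratio = if (mh == 0) NA_real_ else mp / mh,
               p = tryCatch(stats::t.test(vh, vp)$p.value,
                            error = function(e) NA_real_))
  })
  do.call(rbind, out)
}
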