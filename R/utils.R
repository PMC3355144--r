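#' @keywords internal
"_PACKAGE"

## Seed fan-out: every stage/trial seed is derived from one master seed so that
## whole runs are reproducible while trials stay distinct. Kept below 2^31-1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset) * 10007) %% 2147483629L)
}

#' Row-major upper-triangle vectorization
#'
#' Flattens the strict upper triangle of a square matrix in row-major order:
#' (1,2), (1,3), ..., (1,p), (2,3), ... This is the canonical edge order used
#' for all edge feature vectors.
#'
#' @param m square matrix.
#' @return numeric vector of length `p*(p-1)/2`.
#' @seealso [devectorize_edges()], [edge_index()]
#' @export
vectorize_upper <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  t(m)[lower.tri(m)]
}

#' Edge index table for p regions
#'
#' @param p number of regions.
#' @return data.frame with columns `i`, `j` (1-based region indices, `i < j`)
#'   in the row-major upper-triangle order used by [vectorize_upper()].
#' @export
edge_index <- function(p) {
  stopifnot(p >= 2)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) (a + 1L):p), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()] for symmetric matrices; the diagonal is set
#' to `diag_value` (1 for community matrices).
#'
#' @param v edge vector of length `p*(p-1)/2`.
#' @param p matrix dimension.
#' @param diag_value value placed on the diagonal.
#' @return p x p symmetric matrix.
#' @export
devectorize_edges <- function(v, p, diag_value = 1) {
  stopifnot(length(v) == p * (p - 1) / 2)
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- NA_real_  # fill via transpose to honour row-major order
  mt <- t(m)
  mt[lower.tri(mt)] <- v
  m <- t(mt)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

## Position of edge (i, j) in the canonical row-major upper-triangle order of
## a p-region matrix. i, j are 1-based; order within the pair is irrelevant.
edge_position <- function(i, j, p) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  stopifnot(all(lo >= 1), all(hi <= p), all(lo < hi))
  as.integer((lo - 1) * p - lo * (lo - 1) / 2 + (hi - lo))
}

## z-score with population (1/n) denominator; errors on constant input.
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("cannot standardize a constant series")
  (x - m) / s
}

stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
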