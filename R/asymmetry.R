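#' Connectivity profile of a cortical region
#'
#' A region's row of the community matrix over all other cortical regions —
#' its global pattern of functional coupling. Under the default `mirrored`
#' ordering the profiles of the two members of a homolog pair are aligned so
#' that position t in both profiles refers to mutually homologous targets:
#' the partner comes first, then for every other pair the opposite-hemisphere
#' member precedes the same-hemisphere member. The inter-homolog entry
#' K(i, j) is kept in both profiles (it is the leading element of each).
#' `raw` ordering simply follows atlas order.
#'
#' @param K a [community_matrix()] covering all atlas regions.
#' @param region 1-based atlas row index of a paired cortical region.
#' @param atlas a `region_atlas`.
#' @param ordering `"mirrored"` (default) or `"raw"`.
#' @return named numeric vector over the other cortical regions.
#' @export
connectivity_profile <- function(K, region, atlas,
                                 ordering = c("mirrored", "raw")) {
  ordering <- match.arg(ordering)
  Km <- if (inherits(K, "community_matrix")) K$K else K
  stopifnot(nrow(Km) == nrow(atlas))
  partner <- homolog_partner(atlas)
  if (!isTRUE(atlas$cortical[region]) || is.na(partner[region]))
    stop("region ", atlas$name[region], " is not a paired cortical region")
  targets <- profile_targets(region, atlas, partner, ordering)
  stats::setNames(Km[region, targets], atlas$name[targets])
}

profile_targets <- function(region, atlas, partner, ordering) {
  cortical <- which(atlas$cortical & !is.na(partner))
  if (ordering == "raw") return(setdiff(cortical, region))
  own <- atlas$homolog_id[region]
  others <- sort(setdiff(unique(atlas$homolog_id[cortical]), own))
  out <- partner[region]
  same_hemi <- atlas$hemisphere[region]
  for (h in others) {
    members <- cortical[atlas$homolog_id[cortical] == h]
    opp <- members[atlas$hemisphere[members] != same_hemi]
    same <- members[atlas$hemisphere[members] == same_hemi]
    out <- c(out, opp, same)
  }
  out
}

#' Global connectivity asymmetry rho over homolog pairs
#'
#' For each bilateral pair (i, j): `rho = 1 - cor(profile_i, profile_j)`
#' with mirrored profile alignment over the cortical submatrix. Identical
#' profiles give 0 (perfect symmetry); perfectly anticorrelated profiles give
#' 2. A zero-variance profile makes the correlation undefined; the pair is
#' returned as `NA` with a warning and should be excluded from group
#' statistics.
#'
#' @param K a [community_matrix()] covering all atlas regions.
#' @param atlas a `region_atlas`.
#' @param ordering profile alignment, see [connectivity_profile()].
#' @return named numeric vector, one rho per homolog pair in `homolog_id`
#'   order (45 for the default atlas).
#' @export
global_connectivity_asymmetry <- function(K, atlas,
                                          ordering = c("mirrored", "raw")) {
  ordering <- match.arg(ordering)
  pairs <- homolog_pairs(atlas)
  rho <- vapply(seq_len(nrow(pairs)), function(q) {
    pi <- connectivity_profile(K, pairs$left[q], atlas, ordering)
    pj <- connectivity_profile(K, pairs$right[q], atlas, ordering)
    if (stats::sd(pi) == 0 || stats::sd(pj) == 0) return(NA_real_)
    1 - stats::cor(pi, pj)
  }, numeric(1))
  if (anyNA(rho))
    warning("zero-variance connectivity profile: rho undefined for pair(s) ",
            paste(pairs$name[is.na(rho)], collapse = ", "))
  stats::setNames(rho, pairs$name)
}

#' Standardized Euclidean distance between two series
#'
#' Each series is z-scored (zero mean, unit population variance) to remove
#' amplitude and baseline nonstationarity, then
#' `d = sqrt(mean((zx - zy)^2))`. This satisfies the exact identity
#' `d = sqrt(2 * (1 - r))` with r the Pearson correlation, so `d` lies in
#' `[0, 2]`: 0 for identical shapes, sqrt(2) for uncorrelated, 2 for
#' anti-correlated series.
#'
#' @param x,y numeric series of equal length >= 2 with nonzero variance.
#' @return nonnegative scalar.
#' @export
standardized_euclidean <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 2) stop("need at least 2 timepoints")
  sqrt(mean((zscore_pop(x) - zscore_pop(y))^2))
}

#' Pairwise synchronization d over homolog pairs
#'
#' Standardized Euclidean distance between the raw time series of the two
#' members of each bilateral pair; large d means weak interhemispheric
#' synchronization.
#'
#' @param ts a [regional_ts()] or P x T matrix in atlas order.
#' @param atlas a `region_atlas`.
#' @return named numeric vector, one d per homolog pair in `homolog_id` order.
#' @export
pairwise_synchronization <- function(ts, atlas) {
  vals <- if (inherits(ts, "regional_ts")) ts$values else as.matrix(ts)
  stopifnot(nrow(vals) == nrow(atlas))
  pairs <- homolog_pairs(atlas)
  d <- vapply(seq_len(nrow(pairs)), function(q)
    standardized_euclidean(vals[pairs$left[q], ], vals[pairs$right[q], ]),
    numeric(1))
  stats::setNames(d, pairs$name)
}

#' Both asymmetry indices for one subject
#'
#' @param ts a [regional_ts()].
#' @param K the subject's [community_matrix()].
#' @param atlas a `region_atlas`.
#' @return list with `rho`, `d` (named vectors over pairs) and `pair_order`
#'   (the homolog_ids), of class `asymmetry_summary`.
#' @export
asymmetry_summary <- function(ts, K, atlas) {
  pairs <- homolog_pairs(atlas)
  structure(list(rho = global_connectivity_asymmetry(K, atlas),
                 d = pairwise_synchronization(ts, atlas),
                 pair_order = pairs$homolog_id),
            class = "asymmetry_summary")
}
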