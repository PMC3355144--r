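#' Regional time-series container
#'
#' A P x T matrix of regional signals (rows = regions in atlas order, columns
#' = timepoints) plus a subject identifier. Rows must be finite with nonzero
#' variance: a constant region carries no connectivity information and is
#' rejected at construction.
#'
#' @param values numeric P x T matrix.
#' @param subject_id character scalar.
#' @param region_names optional row names (atlas order).
#' @return object of class `regional_ts`.
#' @export
regional_ts <- function(values, subject_id, region_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.character(subject_id) || length(subject_id) != 1)
    stop("subject_id must be a single string")
  if (ncol(values) < 2) stop("need T >= 2 timepoints")
  if (any(!is.finite(values))) stop("non-finite values in time series of ", subject_id)
  v <- apply(values, 1, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)[1]
    nm <- if (!is.null(region_names)) region_names[bad] else
      if (!is.null(rownames(values))) rownames(values)[bad] else as.character(bad)
    stop("constant time series for region ", nm, " in subject ", subject_id)
  }
  if (!is.null(region_names)) rownames(values) <- region_names
  structure(list(values = values, subject_id = subject_id),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> subject %s: %d regions x %d timepoints\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Cohort of subjects with labels and an atlas
#'
#' @param subjects list of [regional_ts()] objects sharing dimensions.
#' @param labels integer vector in `{+1, -1}` (+1 = control, -1 = patient),
#'   one per subject.
#' @param atlas a `region_atlas` whose row count matches the region count.
#' @return object of class `cohort`.
#' @export
cohort <- function(subjects, labels, atlas) {
  stopifnot(is.list(subjects), length(subjects) >= 1)
  labels <- as.integer(labels)
  if (length(labels) != length(subjects))
    stop("labels length must equal subject count")
  if (!all(labels %in% c(1L, -1L))) stop("labels must be +1 or -1")
  dims <- vapply(subjects, function(s) dim(s$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must share region count and timepoint count")
  if (dims[1, 1] != nrow(atlas))
    stop("subject region count (", dims[1, 1], ") does not match atlas (",
         nrow(atlas), ")")
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id: ", ids[duplicated(ids)][1])
  structure(list(subjects = subjects, labels = labels, atlas = atlas),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  d <- dim(x$subjects[[1]]$values)
  cat(sprintf("<cohort> %d subjects (%d control, %d patient), %d regions x %d timepoints\n",
              length(x$subjects), sum(x$labels == 1), sum(x$labels == -1),
              d[1], d[2]))
  invisible(x)
}

subject_ids <- function(co) vapply(co$subjects, `[[`, character(1), "subject_id")

#' Read a cohort from a manifest
#'
#' The manifest is a TSV with header columns `subject_id`, `path`, `label`
#' (`+1`/`1` control, `-1` patient). Each `path` (relative paths resolve
#' against the manifest directory) is a headerless TSV of P rows x T columns
#' in atlas row order.
#'
#' @param manifest_path path to the manifest TSV.
#' @param atlas_path path to the atlas TSV (see [read_atlas()]).
#' @return a validated [cohort()].
#' @export
read_cohort <- function(manifest_path, atlas_path) {
  atlas <- read_atlas(atlas_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  lab_map <- c("+1" = 1L, "1" = 1L, "-1" = -1L)
  labs <- lab_map[trimws(man$label)]
  if (any(is.na(labs)))
    stop("unknown label token: ", man$label[which(is.na(labs))[1]],
         " (expected +1/1/-1)")
  base <- dirname(normalizePath(manifest_path))
  subjects <- lapply(seq_len(nrow(man)), function(r) {
    p <- man$path[r]
    if (!file.exists(p)) p <- file.path(base, man$path[r])
    if (!file.exists(p)) stop("time-series file not found: ", man$path[r])
    vals <- as.matrix(utils::read.delim(p, header = FALSE))
    regional_ts(vals, man$subject_id[r], region_names = atlas$name)
  })
  cohort(subjects, unname(labs), atlas)
}

#' Write a cohort to a directory
#'
#' Writes `atlas.tsv`, `manifest.tsv` and one headerless TSV per subject in
#' the layout read back by [read_cohort()].
#'
#' @param co a [cohort()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(co, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(co$atlas, file.path(dir, "atlas.tsv"))
  ids <- subject_ids(co)
  files <- paste0(ids, ".tsv")
  for (s in seq_along(co$subjects)) {
    utils::write.table(co$subjects[[s]]$values, file.path(dir, files[s]),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  man <- data.frame(subject_id = ids, path = files,
                    label = ifelse(co$labels == 1L, "+1", "-1"))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Community matrix container
#'
#' Symmetric P x P matrix of co-assignment probabilities: entry (i, j) is the
#' estimated probability that regions i and j fall in the same cluster.
#' Entries lie in `[0, 1]`, the diagonal is exactly 1.
#'
#' @param K numeric symmetric matrix.
#' @param config list of the parameters that produced it (fingerprint).
#' @return object of class `community_matrix`.
#' @export
community_matrix <- function(K, config = list()) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  if (min(K) < -1e-12 || max(K) > 1 + 1e-12)
    stop("K entries must lie in [0, 1]")
  if (max(abs(diag(K) - 1)) > 1e-12) stop("K diagonal must be 1")
  K <- (K + t(K)) / 2
  K[K < 0] <- 0; K[K > 1] <- 1
  diag(K) <- 1
  structure(list(K = K, config = config), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d x %d, mean off-diagonal %.3f\n",
              nrow(x$K), ncol(x$K), mean(vectorize_upper(x$K))))
  invisible(x)
}

#' Read / write a community matrix TSV
#'
#' TSV with a header row of region names; `read_matrix(write_matrix(m))`
#' reproduces the matrix to better than 1e-12 elementwise (full precision is
#' written). Reading validates symmetry and the `[0, 1]` range.
#'
#' @param m a [community_matrix()].
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  df <- as.data.frame(format(m$K, digits = 17, trim = TRUE, scientific = TRUE))
  names(df) <- colnames(m$K) %||% paste0("R", seq_len(ncol(m$K)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  K <- as.matrix(df)
  rownames(K) <- colnames(K)
  community_matrix(K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
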