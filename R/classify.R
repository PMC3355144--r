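#' SVM classifier configuration
#'
#' @param kernel `"linear"` (default) or `"rbf"`. With thousands of edge
#'   features and ~10^2 subjects a linear kernel is the appropriate default.
#' @param C regularization constant (> 0, default 1).
#' @param standardize center/scale features using training-fold statistics
#'   only (default TRUE).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(kernel = c("linear", "rbf"), C = 1,
                              standardize = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0)
  structure(list(kernel = kernel, C = C, standardize = isTRUE(standardize)),
            class = "classifier_config")
}

#' Train an SVM and predict test labels
#'
#' Deterministic for fixed inputs and configuration. When standardization is
#' on, column means/SDs come from the training set only and are applied to
#' the test set (no test-set leakage).
#'
#' @param train_x,train_y training features (matrix) and +1/-1 labels.
#' @param test_x test features.
#' @param cfg a [classifier_config()].
#' @return integer vector of predicted labels in `{+1, -1}`.
#' @export
fit_predict <- function(train_x, train_y, test_x, cfg = classifier_config()) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.integer(train_y)
  if (length(unique(train_y)) < 2) stop("training set must contain both classes")
  if (cfg$standardize) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sdv, "/")
  }
  fit <- e1071::svm(train_x, factor(train_y, levels = c(-1L, 1L)),
                    kernel = if (cfg$kernel == "linear") "linear" else "radial",
                    cost = cfg$C, scale = FALSE)
  as.integer(as.character(stats::predict(fit, test_x)))
}

## Assemble the feature matrix for a tag from precomputed cohort features.
## Edge selection (when the tag needs it) must already have been fitted on
## the training subjects only; `sel` / `sel50` are column index vectors.
feature_sets <- c("K_edges", "rho", "d", "K_plus_rho", "crosscorr",
                  "K50_plus_rho")

assemble_features <- function(tag, parts, sel = NULL, sel50 = NULL) {
  switch(tag,
    K_edges      = parts$edges[, sel, drop = FALSE],
    rho          = parts$rho,
    d            = parts$d,
    K_plus_rho   = cbind(parts$edges[, sel, drop = FALSE], parts$rho),
    crosscorr    = parts$crosscorr[, sel, drop = FALSE],
    K50_plus_rho = cbind(parts$edges[, sel50, drop = FALSE], parts$rho),
    stop("unknown feature set: ", tag))
}

needs_selection <- function(tag) tag %in% c("K_edges", "K_plus_rho",
                                            "crosscorr", "K50_plus_rho")

#' Precompute per-subject marker features for a cohort
#'
#' Runs the label-free part of the pipeline once per subject: the consensus
#' community matrix, its cortical edge vector, the asymmetry indices rho and
#' d, and the cross-correlation baseline edges. These depend only on each
#' subject's own data, so computing them before cross-validation cannot leak
#' group information; everything label-dependent (edge selection, feature
#' standardization) stays inside the training folds.
#'
#' @param co a [cohort()].
#' @param community_cfg a [community_config()]; each subject's trial seeds
#'   are derived from its `seed` and the subject index.
#' @return list of class `cohort_features`: `edges`, `crosscorr` (subjects x
#'   E matrices over cortical regions), `rho`, `d` (subjects x pairs),
#'   `edge_index`, `K` (list of [community_matrix()]), `labels`,
#'   `subject_ids`, `atlas`, `config`.
#' @export
cohort_features <- function(co, community_cfg = community_config()) {
  atlas <- co$atlas
  cortical <- which(atlas$cortical)
  n <- length(co$subjects)
  Ks <- vector("list", n)
  edges <- NULL; cc <- NULL; rho <- NULL; dmat <- NULL
  for (s in seq_len(n)) {
    cfg_s <- community_cfg
    cfg_s$seed <- derive_seed(community_cfg$seed, s * 7919L)
    Ks[[s]] <- consensus_community_matrix(co$subjects[[s]], cfg_s, atlas)
    ev <- vectorize_edges(Ks[[s]], include = cortical)
    cv <- crosscorrelation_edges(co$subjects[[s]], include = cortical)
    asym <- asymmetry_summary(co$subjects[[s]], Ks[[s]], atlas)
    if (is.null(edges)) {
      edges <- matrix(0, n, length(ev))
      cc <- matrix(0, n, length(cv))
      rho <- matrix(0, n, length(asym$rho),
                    dimnames = list(NULL, names(asym$rho)))
      dmat <- matrix(0, n, length(asym$d),
                     dimnames = list(NULL, names(asym$d)))
    }
    edges[s, ] <- ev; cc[s, ] <- cv
    rho[s, ] <- asym$rho; dmat[s, ] <- asym$d
  }
  structure(list(edges = edges, crosscorr = cc, rho = rho, d = dmat,
                 edge_index = edge_index(length(cortical)),
                 K = Ks, labels = co$labels, subject_ids = subject_ids(co),
                 atlas = atlas, config = unclass(community_cfg)),
            class = "cohort_features")
}

## one train/test evaluation with nested selection; returns counts
eval_split <- function(parts, labels, train, test, feature_set, n_edges,
                       select_cfg, classifier_cfg, seed) {
  sel <- sel50 <- NULL
  if (needs_selection(feature_set)) {
    src <- if (feature_set == "crosscorr") parts$crosscorr else parts$edges
    ss <- sparse_select(src[train, , drop = FALSE], labels[train],
                        n_keep = if (feature_set == "K50_plus_rho") 50 else n_edges,
                        B = select_cfg$B, frac = select_cfg$frac, seed = seed,
                        aggregate = select_cfg$aggregate,
                        nfolds = select_cfg$nfolds)
    if (feature_set == "K50_plus_rho") sel50 <- ss$selected else sel <- ss$selected
  }
  sub <- function(m, r) m[r, , drop = FALSE]
  tr_parts <- lapply(parts[c("edges", "rho", "d", "crosscorr")], sub, r = train)
  te_parts <- lapply(parts[c("edges", "rho", "d", "crosscorr")], sub, r = test)
  xtr <- assemble_features(feature_set, tr_parts, sel, sel50)
  xte <- assemble_features(feature_set, te_parts, sel, sel50)
  pred <- fit_predict(xtr, labels[train], xte, classifier_cfg)
  truth <- labels[test]
  c(tp = sum(pred == -1L & truth == -1L),  # patients are the positive class
    fn = sum(pred == 1L & truth == -1L),
    tn = sum(pred == 1L & truth == 1L),
    fp = sum(pred == -1L & truth == 1L))
}

report_from_counts <- function(counts, accs, scheme, feature_set, repeats) {
  tot <- colSums(counts)
  sens <- if ((tot["tp"] + tot["fn"]) > 0)
    unname(tot["tp"] / (tot["tp"] + tot["fn"])) else NA_real_
  spec <- if ((tot["tn"] + tot["fp"]) > 0)
    unname(tot["tn"] / (tot["tn"] + tot["fp"])) else NA_real_
  structure(list(accuracy_mean = mean(accs),
                 accuracy_std = if (length(accs) > 1) stats::sd(accs) else 0,
                 sensitivity_mean = sens, specificity_mean = spec,
                 repeats = as.integer(repeats), scheme = scheme,
                 feature_set = feature_set,
                 pooled_counts = as.list(tot),
                 per_repeat_accuracy = as.numeric(accs)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s / %s: accuracy %.1f%% +/- %.1f%% (sens %.1f%%, spec %.1f%%, %d repeats)\n",
              x$scheme, x$feature_set, 100 * x$accuracy_mean,
              100 * x$accuracy_std, 100 * x$sensitivity_mean,
              100 * x$specificity_mean, x$repeats))
  invisible(x)
}

#' Selection configuration for nested cross-validation
#'
#' @param B resamples per selection (default 100).
#' @param frac subsample fraction (default 0.8).
#' @param aggregate aggregation rule, see [sparse_select()].
#' @param nfolds internal CV folds for the penalty.
#' @export
selection_config <- function(B = 100, frac = 0.8, aggregate = "mean_abs",
                             nfolds = 5) {
  list(B = as.integer(B), frac = frac, aggregate = aggregate,
       nfolds = as.integer(nfolds))
}

#' Repeated stratified 50/50 split evaluation
#'
#' The headline protocol: in each repeat, a class-stratified random half of
#' the cohort is used for edge selection, feature standardization and SVM
#' training; the untouched other half is predicted. Every data-dependent step
#' is fitted inside the training half only.
#'
#' @param co a [cohort()], or NULL when `features` is given.
#' @param feature_set one of `"K_edges"`, `"rho"`, `"d"`, `"K_plus_rho"`,
#'   `"crosscorr"`, `"K50_plus_rho"`.
#' @param n_edges number of edges selected inside each training fold
#'   (default 400).
#' @param repeats number of random splits (default 100).
#' @param train_frac training fraction (default 0.5).
#' @param seed RNG seed controlling splits and nested selection.
#' @param community_cfg,select_cfg,classifier_cfg stage configurations.
#' @param features optional precomputed [cohort_features()] (reused across
#'   feature sets and schemes).
#' @return a `classification_report` with mean/std accuracy over repeats and
#'   pooled sensitivity (patients positive) and specificity.
#' @export
repeated_split_cv <- function(co, feature_set = "K_plus_rho", n_edges = 400,
                              repeats = 100, train_frac = 0.5, seed = 1L,
                              community_cfg = community_config(),
                              select_cfg = selection_config(),
                              classifier_cfg = classifier_config(),
                              features = NULL) {
  stopifnot(repeats >= 1, train_frac > 0, train_frac < 1)
  parts <- features %||% cohort_features(co, community_cfg)
  labels <- parts$labels
  n <- length(labels)
  pos <- which(labels == 1L); neg <- which(labels == -1L)
  ntr_pos <- round(train_frac * length(pos))
  ntr_neg <- round(train_frac * length(neg))
  if (ntr_pos < 1 || ntr_neg < 1 || ntr_pos >= length(pos) ||
      ntr_neg >= length(neg))
    stop("train_frac leaves a class empty in train or test")
  accs <- numeric(repeats)
  counts <- matrix(0, repeats, 4, dimnames = list(NULL, c("tp","fn","tn","fp")))
  for (r in seq_len(repeats)) {
    train <- withr::with_seed(derive_seed(seed, 500000L + r),
                              c(sample(pos, ntr_pos), sample(neg, ntr_neg)))
    test <- setdiff(seq_len(n), train)
    ct <- eval_split(parts, labels, train, test, feature_set, n_edges,
                     select_cfg, classifier_cfg,
                     seed = derive_seed(seed, 900000L + r))
    counts[r, ] <- ct
    accs[r] <- (ct["tp"] + ct["tn"]) / sum(ct)
  }
  report_from_counts(counts, accs, "split50", feature_set, repeats)
}

#' Leave-one-out cross-validation
#'
#' Each subject in turn is held out; edge selection and standardization are
#' re-fitted on the remaining subjects, and the held-out subject is
#' predicted. Accuracy is the fraction of subjects predicted correctly.
#'
#' @inheritParams repeated_split_cv
#' @return a `classification_report` (`accuracy_std` is the binary SD across
#'   held-out predictions).
#' @export
loocv <- function(co, feature_set = "K_plus_rho", n_edges = 400, seed = 1L,
                  community_cfg = community_config(),
                  select_cfg = selection_config(),
                  classifier_cfg = classifier_config(),
                  features = NULL) {
  parts <- features %||% cohort_features(co, community_cfg)
  labels <- parts$labels
  n <- length(labels)
  counts <- matrix(0, n, 4, dimnames = list(NULL, c("tp","fn","tn","fp")))
  correct <- numeric(n)
  for (s in seq_len(n)) {
    ct <- eval_split(parts, labels, setdiff(seq_len(n), s), s, feature_set,
                     n_edges, select_cfg, classifier_cfg,
                     seed = derive_seed(seed, 700000L + s))
    counts[s, ] <- ct
    correct[s] <- ct["tp"] + ct["tn"]
  }
  rep <- report_from_counts(counts, correct, "loocv", feature_set, n)
  rep$accuracy_mean <- mean(correct)
  rep$accuracy_std <- stats::sd(correct)
  rep
}

#' Single custom train/test split
#'
#' Evaluates the nested pipeline on an explicit, disjoint train/test split
#' given by subject ids — e.g. training on medicated patients plus controls
#' and testing on unmedicated patients. The test set may be single-class, in
#' which case accuracy equals the corresponding class rate.
#'
#' @param train_ids,test_ids disjoint character vectors of subject ids.
#' @inheritParams repeated_split_cv
#' @return a `classification_report` with `repeats = 1`.
#' @export
custom_split_eval <- function(co, train_ids, test_ids,
                              feature_set = "K_plus_rho", n_edges = 400,
                              seed = 1L,
                              community_cfg = community_config(),
                              select_cfg = selection_config(),
                              classifier_cfg = classifier_config(),
                              features = NULL) {
  parts <- features %||% cohort_features(co, community_cfg)
  ids <- parts$subject_ids
  if (length(intersect(train_ids, test_ids)) > 0)
    stop("train and test ids overlap")
  train <- match(train_ids, ids); test <- match(test_ids, ids)
  if (anyNA(train) || anyNA(test)) stop("unknown subject id")
  if (length(unique(parts$labels[train])) < 2)
    stop("training set must contain both classes")
  ct <- eval_split(parts, parts$labels, train, test, feature_set, n_edges,
                   select_cfg, classifier_cfg, seed = derive_seed(seed, 1L))
  report_from_counts(matrix(ct, 1, dimnames = list(NULL, names(ct))),
                     (ct["tp"] + ct["tn"]) / sum(ct),
                     "custom", feature_set, 1L)
}

#' Accuracy versus number of selected edges
#'
#' Runs the repeated-split protocol over a grid of edge counts with the same
#' nested selection, reporting mean and SD accuracy per grid point.
#'
#' @param n_edges_grid integer grid of edge counts.
#' @inheritParams repeated_split_cv
#' @return data.frame with columns `n_edges`, `accuracy_mean`, `accuracy_std`.
#' @export
edges_sweep <- function(co, n_edges_grid, feature_set = "K_edges",
                        repeats = 20, seed = 1L,
                        community_cfg = community_config(),
                        select_cfg = selection_config(),
                        classifier_cfg = classifier_config(),
                        features = NULL) {
  parts <- features %||% cohort_features(co, community_cfg)
  rows <- lapply(n_edges_grid, function(ne) {
    rep <- repeated_split_cv(NULL, feature_set, n_edges = ne,
                             repeats = repeats, seed = seed,
                             select_cfg = select_cfg,
                             classifier_cfg = classifier_cfg,
                             features = parts)
    data.frame(n_edges = ne, accuracy_mean = rep$accuracy_mean,
               accuracy_std = rep$accuracy_std)
  })
  do.call(rbind, rows)
}

#' Expected performance of a single-link presence rule
#'
#' Closed-form worked example contrasting group-level significance with
#' individual-level prediction: given how many controls and patients carry a
#' particular functional link, the prevalence difference can be large while
#' the rule "link present => control" classifies poorly. The expected
#' accuracy is evaluated on a proportion-preserving held-out fraction and is
#' independent of that fraction.
#'
#' @param n_ctrl,n_pat group sizes.
#' @param n_ctrl_with,n_pat_with subjects in each group carrying the link.
#' @param test_frac held-out fraction (default 0.5; reported counts scale
#'   with it).
#' @return list with `prevalence_difference`, `expected_accuracy`, and the
#'   expected correct counts per class on the test fraction.
#' @examples
#' single_link_rule_eval(80, 56, 100, 50)  # difference 0.20, accuracy ~0.589
#' @export
single_link_rule_eval <- function(n_ctrl, n_ctrl_with, n_pat, n_pat_with,
                                  test_frac = 0.5) {
  stopifnot(n_ctrl > 0, n_pat > 0, n_ctrl_with >= 0, n_pat_with >= 0,
            n_ctrl_with <= n_ctrl, n_pat_with <= n_pat,
            test_frac > 0, test_frac <= 1)
  p_c <- n_ctrl_with / n_ctrl
  p_p <- n_pat_with / n_pat
  correct_ctrl <- test_frac * n_ctrl * p_c        # rule: link => control
  correct_pat <- test_frac * n_pat * (1 - p_p)    # no link => patient
  list(prevalence_difference = p_c - p_p,
       expected_accuracy = (correct_ctrl + correct_pat) /
         (test_frac * (n_ctrl + n_pat)),
       expected_correct_controls = correct_ctrl,
       expected_correct_patients = correct_pat)
}
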