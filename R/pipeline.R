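#' Run the end-to-end marker pipeline from a config file
#'
#' Orchestrates simulate (or load) -> consensus community matrices ->
#' asymmetry indices -> sparse edge selection -> classification, writing all
#' stage artifacts plus a combined JSON report (one classification report per
#' requested feature set). Deterministic given the master seed: a failure in
#' any stage aborts with a stage-named error.
#'
#' The config is JSON or YAML with blocks:
#' \describe{
#'   \item{seed}{master seed; per-stage seeds are derived from it.}
#'   \item{out_dir}{output directory.}
#'   \item{data}{either `simulate: {scenario, n_controls, n_patients,
#'     n_pairs, n_extra, timepoints, ...}` or `manifest` + `atlas` paths.}
#'   \item{community}{`k`, `trials`, `standardize_rows` (optional).}
#'   \item{selection}{`n_edges`, `resamples`, `frac` (optional).}
#'   \item{classify}{`feature_sets` (vector), `scheme` (`split50`, `loocv`
#'     or both), `repeats`, `train_frac` (optional).}
#' }
#'
#' @param config path to a JSON/YAML config file, or an equivalent list.
#' @return the report list, invisibly; `report.json` and stage outputs are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("[config] file not found: ", config)
    if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## --- data stage -----------------------------------------------------
  gt <- NULL
  co <- tryCatch({
    if (!is.null(cfg$data$simulate)) {
      s <- cfg$data$simulate
      atlas <- if (!is.null(s$n_pairs))
        synthetic_atlas(s$n_pairs, s$n_extra %||% 0) else aal_atlas()
      sargs <- list(scenario = s$scenario %||% "custom",
                    n_controls = s$n_controls %||% 80,
                    n_patients = s$n_patients %||% 100,
                    atlas = atlas,
                    timepoints = s$timepoints %||% 250,
                    seed = derive_seed(seed, 1L))
      for (f in c("n_blocks", "n_flipped", "noise_sd", "coupling",
                  "asymmetry_ctrl", "asymmetry_pat", "ar_phi"))
        if (!is.null(s[[f]])) sargs[[f]] <- s[[f]]
      scfg <- do.call(synth_config, sargs)
      gen <- generate_cohort(scfg)
      gt <- gen$ground_truth  # tryCatch evaluates in this frame
      write_cohort(gen$cohort, file.path(out_dir, "cohort"))
      gen$cohort
    } else {
      if (is.null(cfg$data$manifest)) stop("config needs data$simulate or data$manifest")
      if (!file.exists(cfg$data$manifest))
        stop("manifest not found: ", cfg$data$manifest)
      read_cohort(cfg$data$manifest, cfg$data$atlas)
    }
  }, error = function(e) stop_stage("data", e))

  ## --- community + asymmetry (per-subject, label-free) ----------------
  parts <- tryCatch({
    ccfg <- community_config(k = cfg$community$k %||% 30,
                             L = cfg$community$trials %||% 500,
                             seed = derive_seed(seed, 2L),
                             standardize_rows =
                               cfg$community$standardize_rows %||% TRUE)
    cohort_features(co, ccfg)
  }, error = function(e) stop_stage("community", e))
  tryCatch({
    kdir <- file.path(out_dir, "community")
    dir.create(kdir, showWarnings = FALSE)
    for (s in seq_along(parts$K))
      write_matrix(parts$K[[s]], file.path(kdir, paste0(parts$subject_ids[s], "_K.tsv")))
    asym <- data.frame(subject_id = parts$subject_ids,
                       label = parts$labels)
    asym <- cbind(asym,
                  stats::setNames(as.data.frame(parts$rho),
                                  paste0("rho_", colnames(parts$rho))),
                  stats::setNames(as.data.frame(parts$d),
                                  paste0("d_", colnames(parts$d))))
    utils::write.table(asym, file.path(out_dir, "asymmetry.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }, error = function(e) stop_stage("asymmetry", e))

  ## --- whole-cohort selection (descriptive ranking) -------------------
  sel_cfg <- selection_config(B = cfg$selection$resamples %||% 100,
                              frac = cfg$selection$frac %||% 0.8)
  n_edges <- cfg$selection$n_edges %||% 400
  sel <- tryCatch({
    ss <- sparse_select(parts$edges, parts$labels,
                        n_keep = min(n_edges, ncol(parts$edges)),
                        B = sel_cfg$B, frac = sel_cfg$frac,
                        seed = derive_seed(seed, 3L))
    jsonlite::write_json(
      list(selected = ss$selected, coef = ss$coef,
           n_selected = ss$n_selected, resamples = ss$resamples,
           subsample_fraction = ss$subsample_fraction,
           lambda_rule = ss$lambda_rule, seed = derive_seed(seed, 3L)),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    ss
  }, error = function(e) stop_stage("select", e))

  ## --- classification -------------------------------------------------
  reports <- tryCatch({
    fsets <- cfg$classify$feature_sets %||% "K_plus_rho"
    schemes <- cfg$classify$scheme %||% "split50"
    repeats <- cfg$classify$repeats %||% 100
    out <- list()
    for (fs in fsets) for (sc in schemes) {
      rep <- if (sc == "split50")
        repeated_split_cv(NULL, fs, n_edges = min(n_edges, ncol(parts$edges)),
                          repeats = repeats,
                          train_frac = cfg$classify$train_frac %||% 0.5,
                          seed = derive_seed(seed, 4L),
                          select_cfg = sel_cfg, features = parts)
      else if (sc == "loocv")
        loocv(NULL, fs, n_edges = min(n_edges, ncol(parts$edges)),
              seed = derive_seed(seed, 5L), select_cfg = sel_cfg,
              features = parts)
      else stop("unknown scheme: ", sc)
      out[[paste(fs, sc, sep = ".")]] <- unclass(rep)
    }
    out
  }, error = function(e) stop_stage("classify", e))

  report <- list(fingerprint = list(seed = seed,
                                    community = parts$config,
                                    selection = sel_cfg,
                                    n_edges = n_edges),
                 n_subjects = length(parts$labels),
                 n_controls = sum(parts$labels == 1L),
                 n_patients = sum(parts$labels == -1L),
                 scenario = if (!is.null(gt)) gt$scenario else "user_data",
                 classification = reports)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
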