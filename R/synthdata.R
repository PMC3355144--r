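#' Synthetic cohort configuration
#'
#' Defines a two-group cohort of region-parcellated time series with planted
#' latent community structure, planted group-discriminative edges, and
#' planted homolog asymmetry.
#'
#' Construction per subject: each latent block b has an independent
#' standardized AR(1) signal s_b; region i's series is
#' `coupling * s_b(i) + noise_sd * eps`. The block map of controls assigns
#' homolog pairs to blocks; each planted discriminative edge occupies its own
#' two-pair block, and in patients the second pair of that block is moved to
#' a fresh block, so that exactly the four left/right edge combinations of
#' the planted pair differ in co-membership between groups. For each homolog
#' pair the right-hemisphere series mixes its left partner's latent block
#' signal with an independent signal in ratio `(1 - a) : a` (variance
#' normalized) for the group's asymmetry parameter a, so a = 0 gives
#' perfectly mirrored hemispheres and a = 1 fully decoupled ones.
#'
#' Scenario presets fix the effect parameters: `strong` (clear block
#' structure, 10 planted edges, patient asymmetry well above control),
#' `weak` (noisier, 4 planted edges, small asymmetry gap) and `null` (no
#' planted edges, equal asymmetry — the leakage-detection condition).
#'
#' @param scenario `"custom"`, `"strong"`, `"weak"` or `"null"`.
#' @param n_controls,n_patients group sizes (defaults 80 / 100).
#' @param atlas a `region_atlas` (default [aal_atlas()], 116 regions).
#' @param timepoints series length T (default 250).
#' @param n_blocks latent blocks for the non-planted pairs (default 8).
#' @param noise_sd residual scale.
#' @param coupling shared-signal weight in (0, 1).
#' @param n_flipped number of planted discriminative edges (ignored if
#'   `flipped_pairs` given).
#' @param flipped_pairs optional explicit list of homolog-pair id pairs
#'   `(q1, q2)` to plant; default drawn from the seed.
#' @param asymmetry_ctrl,asymmetry_pat homolog decoupling a in `[0, 1]` per
#'   group.
#' @param ar_phi lag-1 coefficient of the latent AR(1) signals (default 0.3,
#'   mimicking band-passed haemodynamic smoothness; 0 gives white noise).
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(scenario = c("custom", "strong", "weak", "null"),
                         n_controls = 80, n_patients = 100,
                         atlas = aal_atlas(), timepoints = 250,
                         n_blocks = 8, noise_sd = 0.6, coupling = 0.85,
                         n_flipped = 10, flipped_pairs = NULL,
                         asymmetry_ctrl = 0.1, asymmetry_pat = 0.3,
                         ar_phi = 0.3, seed = 1L) {
  scenario <- match.arg(scenario)
  ## scenario presets fix the effect parameters; explicitly passed arguments
  ## still win, so test fixtures can scale the planted-edge count down
  if (scenario == "strong") {
    if (missing(noise_sd)) noise_sd <- 0.4
    if (missing(coupling)) coupling <- 0.9
    if (missing(n_flipped)) n_flipped <- 10
    if (missing(asymmetry_ctrl)) asymmetry_ctrl <- 0.05
    if (missing(asymmetry_pat)) asymmetry_pat <- 0.45
  } else if (scenario == "weak") {
    if (missing(noise_sd)) noise_sd <- 0.9
    if (missing(coupling)) coupling <- 0.6
    if (missing(n_flipped)) n_flipped <- 4
    if (missing(asymmetry_ctrl)) asymmetry_ctrl <- 0.1
    if (missing(asymmetry_pat)) asymmetry_pat <- 0.2
  } else if (scenario == "null") {
    if (missing(noise_sd)) noise_sd <- 0.6
    if (missing(coupling)) coupling <- 0.8
    n_flipped <- 0; flipped_pairs <- NULL
    asymmetry_ctrl <- asymmetry_pat <- 0.1
  }
  stopifnot(n_controls >= 1, n_patients >= 1, timepoints >= 2,
            noise_sd >= 0, coupling > 0, coupling < 1,
            asymmetry_ctrl >= 0, asymmetry_ctrl <= 1,
            asymmetry_pat >= 0, asymmetry_pat <= 1,
            abs(ar_phi) < 1, n_blocks >= 1)
  n_pairs <- nrow(homolog_pairs(atlas))
  if (2 * n_flipped > n_pairs)
    stop("not enough homolog pairs for ", n_flipped, " planted edges")
  structure(list(scenario = scenario, n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients), atlas = atlas,
                 timepoints = as.integer(timepoints),
                 n_blocks = as.integer(n_blocks), noise_sd = noise_sd,
                 coupling = coupling, n_flipped = as.integer(n_flipped),
                 flipped_pairs = flipped_pairs,
                 asymmetry_ctrl = asymmetry_ctrl,
                 asymmetry_pat = asymmetry_pat, ar_phi = ar_phi,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## standardized AR(1) series (marginal variance 1)
ar1_series <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  e <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  e[1] <- stats::rnorm(1)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

## Resolve the planted structure: block map per group (over homolog pairs and
## unpaired regions) plus the planted edge list. Deterministic given cfg$seed.
resolve_structure <- function(cfg) {
  pairs <- homolog_pairs(cfg$atlas)
  nq <- nrow(pairs)
  planted_q <- if (!is.null(cfg$flipped_pairs)) cfg$flipped_pairs else
    if (cfg$n_flipped > 0)
      withr::with_seed(derive_seed(cfg$seed, 17L), {
        qs <- sample.int(nq, 2 * cfg$n_flipped)
        split(qs, rep(seq_len(cfg$n_flipped), each = 2))
      }) else list()
  planted_block <- seq_along(planted_q)               # one block per planted edge
  free_q <- setdiff(seq_len(nq), unlist(planted_q))
  n_planted <- length(planted_q)
  free_blocks <- n_planted + seq_len(cfg$n_blocks)
  pair_block_ctrl <- integer(nq)
  for (e in seq_len(n_planted)) pair_block_ctrl[planted_q[[e]]] <- e
  if (length(free_q))
    pair_block_ctrl[free_q] <- free_blocks[1 + (seq_along(free_q) - 1) %%
                                             cfg$n_blocks]
  pair_block_pat <- pair_block_ctrl
  fresh <- n_planted + cfg$n_blocks
  for (e in seq_len(n_planted))                        # move 2nd pair out
    pair_block_pat[planted_q[[e]][2]] <- fresh + e
  ## unpaired regions get shared blocks (identical across groups)
  unpaired <- which(is.na(homolog_partner(cfg$atlas)))
  unpaired_block <- if (length(unpaired))
    free_blocks[1 + (seq_along(unpaired) - 1) %% cfg$n_blocks] else integer(0)
  total_blocks <- fresh + n_planted
  flipped_edges <- if (n_planted)
    do.call(rbind, lapply(seq_len(n_planted), function(e) {
      q <- planted_q[[e]]
      data.frame(edge = e,
                 i = pairs$left[q[1]], j = pairs$left[q[2]],
                 name_i = cfg$atlas$name[pairs$left[q[1]]],
                 name_j = cfg$atlas$name[pairs$left[q[2]]])
    })) else data.frame(edge = integer(), i = integer(), j = integer(),
                        name_i = character(), name_j = character())
  list(pairs = pairs, planted_q = planted_q,
       pair_block = list(control = pair_block_ctrl, patient = pair_block_pat),
       unpaired = unpaired, unpaired_block = unpaired_block,
       total_blocks = total_blocks, flipped_edges = flipped_edges)
}

#' Generate one synthetic subject
#'
#' @param cfg a [synth_config()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed RNG seed for this subject's signals.
#' @param structure internal planted structure; recomputed from `cfg` if
#'   missing.
#' @param subject_id identifier.
#' @return a [regional_ts()].
#' @export
generate_subject <- function(cfg, group = c("control", "patient"),
                             subject_seed = cfg$seed, structure = NULL,
                             subject_id = "s1") {
  group <- match.arg(group)
  st <- structure %||% resolve_structure(cfg)
  a <- if (group == "control") cfg$asymmetry_ctrl else cfg$asymmetry_pat
  pair_block <- st$pair_block[[group]]
  P <- nrow(cfg$atlas); T <- cfg$timepoints
  vals <- withr::with_seed(subject_seed, {
    S <- vapply(seq_len(st$total_blocks), function(b)
      ar1_series(T, cfg$ar_phi), numeric(T))       # T x blocks
    out <- matrix(0, P, T)
    mix_norm <- sqrt((1 - a)^2 + a^2)
    for (q in seq_len(nrow(st$pairs))) {
      sb <- S[, pair_block[q]]
      l <- st$pairs$left[q]; r <- st$pairs$right[q]
      out[l, ] <- cfg$coupling * sb
      u <- ar1_series(T, cfg$ar_phi)               # pair-specific decoupler
      mix <- if (mix_norm > 0) ((1 - a) * sb + a * u) / mix_norm else sb
      out[r, ] <- cfg$coupling * mix
    }
    for (ui in seq_along(st$unpaired))
      out[st$unpaired[ui], ] <- cfg$coupling * S[, st$unpaired_block[ui]]
    out + cfg$noise_sd * matrix(stats::rnorm(P * T), P, T)
  })
  regional_ts(vals, subject_id, region_names = cfg$atlas$name)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Controls (label +1) come first, then patients (label -1). Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `cohort` (a [cohort()]) and `ground_truth`: the planted
#'   edge list (`flipped_edges`, region indices 1-based plus names and their
#'   cortical edge-vector columns), per-group homolog-pair block maps, the
#'   per-group asymmetry parameters and the scenario.
#' @export
generate_cohort <- function(cfg) {
  st <- resolve_structure(cfg)
  n <- cfg$n_controls + cfg$n_patients
  groups <- rep(c("control", "patient"), c(cfg$n_controls, cfg$n_patients))
  subjects <- lapply(seq_len(n), function(s)
    generate_subject(cfg, groups[s],
                     subject_seed = derive_seed(cfg$seed, 1000L + s),
                     structure = st,
                     subject_id = sprintf("%s_%03d",
                                          ifelse(groups[s] == "control", "ctrl", "pat"),
                                          s)))
  labels <- ifelse(groups == "control", 1L, -1L)
  co <- cohort(subjects, labels, cfg$atlas)
  fe <- st$flipped_edges
  realizations <- list()
  if (nrow(fe)) {
    cortical <- which(cfg$atlas$cortical)
    fe$edge_column <- edge_position(match(fe$i, cortical),
                                    match(fe$j, cortical), length(cortical))
    ## each planted link joins two bilateral pairs, so it appears in K as
    ## four exchangeable region-level edges (L-L, L-R, R-L, R-R)
    realizations <- lapply(st$planted_q, function(q) {
      r1 <- match(c(st$pairs$left[q[1]], st$pairs$right[q[1]]), cortical)
      r2 <- match(c(st$pairs$left[q[2]], st$pairs$right[q[2]]), cortical)
      sort(as.vector(outer(r1, r2, edge_position, p = length(cortical))))
    })
  } else fe$edge_column <- integer(0)
  gt <- list(scenario = cfg$scenario, flipped_edges = fe,
             edge_realizations = realizations,
             pair_block = st$pair_block, planted_pairs = st$planted_q,
             asymmetry = c(control = cfg$asymmetry_ctrl,
                           patient = cfg$asymmetry_pat),
             seed = cfg$seed)
  list(cohort = co, ground_truth = gt)
}

#' Write a synthetic cohort and its ground truth to disk
#'
#' Writes the manifest/TSV layout of [write_cohort()] plus
#' `ground_truth.json`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
simulate_to_dir <- function(cfg, dir) {
  gen <- generate_cohort(cfg)
  man <- write_cohort(gen$cohort, dir)
  gt <- gen$ground_truth
  gt$pair_block <- lapply(gt$pair_block, as.integer)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Recovery of planted discriminative links by an edge selection
#'
#' A planted link couples two bilateral region pairs, so in the community
#' matrix it manifests as four statistically exchangeable region-level edges
#' (left-left, left-right, right-left, right-right); sparse regression
#' distributes weight among them. At the default `"link"` level a planted
#' link counts as recovered when any of its four edge realizations is
#' selected; `"column"` counts only the canonical left-left column.
#'
#' @param selection a [sparse_select()] result (or vector of selected edge
#'   columns).
#' @param ground_truth the `ground_truth` element of [generate_cohort()].
#' @param level `"link"` (default) or `"column"`.
#' @return list with `n_planted`, `n_recovered`, `fraction`.
#' @export
planted_edge_recovery <- function(selection, ground_truth,
                                  level = c("link", "column")) {
  level <- match.arg(level)
  sel <- if (inherits(selection, "sparse_selection")) selection$selected else
    as.integer(selection)
  hits <- if (level == "column")
    ground_truth$flipped_edges$edge_column %in% sel
  else
    vapply(ground_truth$edge_realizations, function(cols) any(cols %in% sel),
           logical(1))
  list(n_planted = length(hits), n_recovered = sum(hits),
       fraction = if (length(hits)) mean(hits) else NA_real_)
}
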