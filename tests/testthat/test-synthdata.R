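test_that("generator defaults mirror the study conditions", {
  cfg <- synth_config()
  expect_equal(cfg$n_controls, 80L)
  expect_equal(cfg$n_patients, 100L)
  expect_equal(nrow(cfg$atlas), 116)
  expect_equal(cfg$timepoints, 250L)
  ## null preset: nothing planted, equal asymmetry
  cfg0 <- synth_config("null")
  expect_equal(cfg0$n_flipped, 0L)
  expect_equal(cfg0$asymmetry_ctrl, cfg0$asymmetry_pat)
})

test_that("cohort generation is deterministic with labelled ground truth", {
  cfg <- synth_config("strong", n_controls = 4, n_patients = 5,
                      atlas = synthetic_atlas(6), timepoints = 50,
                      n_blocks = 2, n_flipped = 2, seed = 77)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$subjects[[3]]$values,
                   g2$cohort$subjects[[3]]$values)
  expect_equal(g1$cohort$labels, c(rep(1L, 4), rep(-1L, 5)))
  expect_equal(nrow(g1$ground_truth$flipped_edges), 2)
  expect_length(g1$ground_truth$edge_realizations, 2)
  expect_true(all(lengths(g1$ground_truth$edge_realizations) == 4))
  ## planted links join two distinct pairs, co-membership differs by group
  pb <- g1$ground_truth$pair_block
  for (q in g1$ground_truth$planted_pairs) {
    expect_equal(pb$control[q[1]], pb$control[q[2]])
    expect_false(pb$patient[q[1]] == pb$patient[q[2]])
  }
})

test_that("homolog mixing drives d from 0 to sqrt(2) as a goes 0 to 1", {
  atlas <- synthetic_atlas(8)
  base <- list(atlas = atlas, timepoints = 300, n_blocks = 3, n_flipped = 0)
  cfg0 <- synth_config("custom", n_controls = 2, n_patients = 1,
                       atlas = atlas, timepoints = 300, n_blocks = 3,
                       n_flipped = 0, noise_sd = 0, asymmetry_ctrl = 0,
                       asymmetry_pat = 0, seed = 5)
  s0 <- generate_subject(cfg0, "control", subject_seed = 9)
  expect_equal(unname(pairwise_synchronization(s0, atlas)), rep(0, 8))
  cfg1 <- synth_config("custom", n_controls = 2, n_patients = 1,
                       atlas = atlas, timepoints = 300, n_blocks = 3,
                       n_flipped = 0, noise_sd = 0, asymmetry_ctrl = 1,
                       asymmetry_pat = 1, seed = 5)
  d1 <- sapply(1:6, function(s)
    mean(pairwise_synchronization(generate_subject(cfg1, "control",
                                                   subject_seed = s), atlas)))
  expect_lt(abs(mean(d1) - sqrt(2)), 0.12)
  ## monotone non-decreasing group-mean d over an asymmetry grid
  md <- sapply(c(0, 0.3, 0.6, 0.9), function(a) {
    cfg <- synth_config("custom", n_controls = 5, n_patients = 1,
                        atlas = atlas, timepoints = 150, n_blocks = 3,
                        n_flipped = 0, asymmetry_ctrl = a, asymmetry_pat = a,
                        seed = 11)
    gen <- generate_cohort(cfg)
    mean(sapply(gen$cohort$subjects[1:5], function(s)
      mean(pairwise_synchronization(s, atlas))))
  })
  expect_true(all(diff(md) > 0))
})

test_that("group-mean rho increases with the asymmetry parameter", {
  atlas <- synthetic_atlas(6)
  mr <- sapply(c(0.05, 0.5, 0.95), function(a) {
    cfg <- synth_config("custom", n_controls = 4, n_patients = 1,
                        atlas = atlas, timepoints = 100, n_blocks = 3,
                        n_flipped = 0, asymmetry_ctrl = a, asymmetry_pat = a,
                        seed = 19)
    gen <- generate_cohort(cfg)
    mean(sapply(gen$cohort$subjects[1:4], function(s) {
      K <- consensus_community_matrix(s, community_config(k = 4, L = 25,
                                                          seed = 20), atlas)
      mean(global_connectivity_asymmetry(K, atlas))
    }))
  })
  expect_true(all(diff(mr) > 0))
})

test_that("group-mean community matrices differ exactly on planted links", {
  gen <- small_strong_cohort(seed = 51, n_per_group = 12, n_pairs = 8,
                             n_flipped = 3, timepoints = 100)
  parts <- cohort_features(gen$cohort, community_config(k = 5, L = 30, seed = 52))
  mh <- colMeans(parts$edges[parts$labels == 1, , drop = FALSE])
  mp <- colMeans(parts$edges[parts$labels == -1, , drop = FALSE])
  gap <- abs(mh - mp)
  planted_cols <- unlist(gen$ground_truth$edge_realizations)
  expect_gt(min(gap[planted_cols]), 0.5)   # co-membership flips ~1 -> ~0
  expect_lt(max(gap[-planted_cols]), 0.35) # everything else is stable
  ## direction: planted links are present in controls, absent in patients
  expect_true(all(mh[planted_cols] > mp[planted_cols]))
})

test_that("simulated cohorts round-trip through disk with ground truth", {
  dir <- withr::local_tempdir()
  cfg <- synth_config("weak", n_controls = 3, n_patients = 3,
                      atlas = synthetic_atlas(4), timepoints = 40,
                      n_blocks = 2, n_flipped = 1, seed = 61)
  simulate_to_dir(cfg, dir)
  co <- read_cohort(file.path(dir, "manifest.tsv"), file.path(dir, "atlas.tsv"))
  expect_equal(length(co$subjects), 6)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$scenario, "weak")
  expect_equal(nrow(gt$flipped_edges), 1)
})
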