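test_that("SVM separates well-separated blobs and memorizes its training set", {
  n <- 40
  labels <- rep(c(1L, -1L), each = n / 2)
  x <- withr::with_seed(3, cbind(rnorm(n, mean = 10 * labels, sd = 0.5),
                                 rnorm(n, sd = 0.5)))
  test_x <- withr::with_seed(4, cbind(rnorm(20, mean = 10 * rep(c(1, -1), 10),
                                            sd = 0.5), rnorm(20, sd = 0.5)))
  expect_equal(fit_predict(x, labels, test_x), rep(c(1L, -1L), 10))
  expect_equal(fit_predict(x, labels, x), labels)
  expect_error(fit_predict(x, rep(1L, n), x), "both classes")
})

test_that("SVM accuracy sits in the binomial null band on label-permuted noise", {
  correct <- total <- 0
  for (s in 1:50) {
    x <- withr::with_seed(200 + s, matrix(rnorm(60 * 5), 60, 5))
    y <- withr::with_seed(300 + s, sample(rep(c(1L, -1L), 30)))
    pred <- fit_predict(x[1:40, ], y[1:40], x[41:60, ])
    correct <- correct + sum(pred == y[41:60])
    total <- total + 20
  }
  band <- 1.96 * sqrt(0.25 / total)
  expect_lt(abs(correct / total - 0.5), band + 0.02)
})

test_that("nested split evaluation is deterministic and internally consistent", {
  gen <- small_strong_cohort(seed = 31, n_per_group = 10, n_pairs = 6,
                             n_flipped = 2, timepoints = 80)
  parts <- cohort_features(gen$cohort, community_config(k = 4, L = 20, seed = 32))
  rep1 <- repeated_split_cv(NULL, "K_plus_rho", n_edges = 10, repeats = 3,
                            seed = 33, select_cfg = selection_config(B = 8),
                            features = parts)
  rep2 <- repeated_split_cv(NULL, "K_plus_rho", n_edges = 10, repeats = 3,
                            seed = 33, select_cfg = selection_config(B = 8),
                            features = parts)
  expect_identical(rep1, rep2)
  ## sensitivity/specificity recombine to pooled accuracy via class priors
  ct <- rep1$pooled_counts
  n_pat <- ct$tp + ct$fn; n_ctrl <- ct$tn + ct$fp
  expect_equal(mean(rep1$per_repeat_accuracy),
               (rep1$sensitivity_mean * n_pat + rep1$specificity_mean * n_ctrl) /
                 (n_pat + n_ctrl), tolerance = 1e-12)
  expect_true(all(c(rep1$accuracy_mean, rep1$sensitivity_mean,
                    rep1$specificity_mean) >= 0))
  expect_true(all(c(rep1$accuracy_mean, rep1$sensitivity_mean,
                    rep1$specificity_mean) <= 1))
})

test_that("LOOCV classifies a tiny separable cohort perfectly", {
  rho <- matrix(c(5, 5.2, -5, -5.1), 4, 3)  # 4 subjects, 3 asymmetry features
  parts <- fake_parts(edges = matrix(rnorm(4 * 6), 4, 6), rho = rho,
                      labels = c(1, 1, -1, -1))
  rep <- loocv(NULL, "rho", seed = 5, features = parts)
  expect_equal(rep$accuracy_mean, 1)
  expect_equal(rep$sensitivity_mean, 1)
  expect_equal(rep$specificity_mean, 1)
  expect_equal(rep$scheme, "loocv")
})

test_that("custom splits validate ids and handle single-class test sets", {
  rho <- rbind(matrix(5, 6, 2), matrix(-5, 6, 2)) +
    withr::with_seed(8, matrix(rnorm(24, sd = 0.1), 12, 2))
  parts <- fake_parts(edges = withr::with_seed(9, matrix(rnorm(12 * 6), 12, 6)),
                      rho = rho, labels = rep(c(1, -1), each = 6))
  ids <- parts$subject_ids
  rep <- custom_split_eval(NULL, train_ids = ids[c(1:5, 7:11)],
                           test_ids = ids[12], feature_set = "rho",
                           features = parts)
  ## all-patient test set: accuracy equals sensitivity
  expect_equal(rep$accuracy_mean, rep$sensitivity_mean)
  expect_equal(rep$accuracy_mean, 1)
  expect_error(custom_split_eval(NULL, ids[1:6], ids[6:8], "rho",
                                 features = parts), "overlap")
  expect_error(custom_split_eval(NULL, ids[1:6], c("nope"), "rho",
                                 features = parts), "unknown subject id")
  expect_error(custom_split_eval(NULL, ids[1:5], ids[7], "rho",
                                 features = parts), "both classes")
})

test_that("the edges sweep reduces to no selection at the full edge count", {
  gen <- small_strong_cohort(seed = 41, n_per_group = 8, n_pairs = 4,
                             n_flipped = 1, timepoints = 60)
  parts <- cohort_features(gen$cohort, community_config(k = 3, L = 15, seed = 42))
  E <- ncol(parts$edges)
  tab <- edges_sweep(NULL, n_edges_grid = c(4, E), repeats = 2, seed = 43,
                     select_cfg = selection_config(B = 5), features = parts)
  expect_equal(tab$n_edges, c(4, E))
  ## selecting all E edges spans the full feature set
  ss <- sparse_select(parts$edges, parts$labels, n_keep = E, B = 5, seed = 44)
  expect_setequal(ss$selected, seq_len(E))
  ## fixed-seed reproducibility
  tab2 <- edges_sweep(NULL, n_edges_grid = c(4, E), repeats = 2, seed = 43,
                      select_cfg = selection_config(B = 5), features = parts)
  expect_identical(tab, tab2)
})

test_that("the single-link rule mirrors the prevalence-vs-accuracy contrast", {
  r <- single_link_rule_eval(80, 56, 100, 50, test_frac = 0.5)
  expect_equal(r$prevalence_difference, 0.20, tolerance = 1e-12)
  expect_equal(r$expected_accuracy, 53 / 90, tolerance = 1e-12)
  expect_equal(r$expected_correct_controls, 28)
  expect_equal(r$expected_correct_patients, 25)
  ## a perfectly informative link classifies perfectly
  r2 <- single_link_rule_eval(10, 10, 10, 0, 0.5)
  expect_equal(r2$prevalence_difference, 1)
  expect_equal(r2$expected_accuracy, 1)
  ## the expected accuracy does not depend on the held-out fraction
  expect_equal(single_link_rule_eval(80, 56, 100, 50, 0.2)$expected_accuracy,
               53 / 90, tolerance = 1e-12)
  expect_error(single_link_rule_eval(10, 11, 10, 0), "n_ctrl_with")
})
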