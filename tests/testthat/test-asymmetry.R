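test_that("connectivity profiles follow the mirrored pair alignment", {
  ## 4-region toy: A, A' (pair 1), B, B' (pair 2)
  atlas <- synthetic_atlas(2)
  K <- random_K(4, seed = 3)
  pA <- connectivity_profile(K, 1, atlas)
  pA2 <- connectivity_profile(K, 2, atlas)
  ## profile(A) = [K(A,A'), K(A,B'), K(A,B)]; profile(A') = [K(A',A), K(A',B), K(A',B')]
  expect_equal(unname(pA), c(K[1, 2], K[1, 4], K[1, 3]))
  expect_equal(unname(pA2), c(K[2, 1], K[2, 3], K[2, 4]))
  ## raw ordering is the same multiset, differently permuted
  praw <- connectivity_profile(K, 1, atlas, ordering = "raw")
  expect_equal(sort(unname(praw)), sort(unname(pA)))
  expect_equal(unname(praw), c(K[1, 2], K[1, 3], K[1, 4]))
  expect_error(connectivity_profile(random_K(5, seed = 4), 5,
                                    synthetic_atlas(2, 1)),
               "not a paired cortical region")
})

test_that("rho hits its analytic extremes and matches a hand Pearson oracle", {
  atlas <- synthetic_atlas(3)
  ## mirror-symmetric K: every profile pair identical => rho = 0
  Ks <- diag(6)
  within <- rbind(c(1, 3), c(2, 4), c(1, 5), c(2, 6), c(3, 5), c(4, 6))
  vals <- c(0.7, 0.7, 0.2, 0.2, 0.5, 0.5)
  for (r in seq_len(nrow(within))) {
    Ks[within[r, 1], within[r, 2]] <- vals[r]
    Ks[within[r, 2], within[r, 1]] <- vals[r]
  }
  rho <- global_connectivity_asymmetry(Ks, atlas)
  expect_equal(length(rho), 3)
  expect_equal(unname(rho[1]), 0, tolerance = 1e-12)
  ## engineered anti-correlated profiles for pair 1 => rho = 2
  Ka <- diag(6)
  set_sym <- function(K, i, j, v) { K[i, j] <- v; K[j, i] <- v; K }
  Ka <- set_sym(Ka, 1, 2, 0.5)
  prof1 <- c(0.9, 0.8, 0.1, 0.3)           # K(1,4), K(1,3), K(1,6), K(1,5)
  Ka <- set_sym(Ka, 1, 4, prof1[1]); Ka <- set_sym(Ka, 1, 3, prof1[2])
  Ka <- set_sym(Ka, 1, 6, prof1[3]); Ka <- set_sym(Ka, 1, 5, prof1[4])
  ## mirrored targets of region 2 are (3, 4, 5, 6); set to 1 - prof1
  Ka <- set_sym(Ka, 2, 3, 1 - prof1[1]); Ka <- set_sym(Ka, 2, 4, 1 - prof1[2])
  Ka <- set_sym(Ka, 2, 5, 1 - prof1[3]); Ka <- set_sym(Ka, 2, 6, 1 - prof1[4])
  rho_a <- global_connectivity_asymmetry(Ka, atlas)
  expect_equal(unname(rho_a[1]), 2, tolerance = 1e-12)
  ## arbitrary K: 1 - rho equals the independent hand-formula Pearson r
  K <- random_K(6, seed = 9)
  p1 <- connectivity_profile(K, 1, atlas)
  p2 <- connectivity_profile(K, 2, atlas)
  rho_k <- global_connectivity_asymmetry(K, atlas)
  expect_equal(unname(rho_k[1]), 1 - pearson_oracle(p1, p2), tolerance = 1e-12)
  expect_true(all(rho_k >= 0 & rho_k <= 2))
})

test_that("rho flags zero-variance profiles as missing", {
  atlas <- synthetic_atlas(3)
  K <- diag(6)  # all off-diagonal zero: profiles are constant
  expect_warning(rho <- global_connectivity_asymmetry(K, atlas),
                 "zero-variance")
  expect_true(all(is.na(rho)))
})

test_that("standardized Euclidean distance satisfies d = sqrt(2(1-r))", {
  x <- c(1, 2, 3, 4)
  expect_equal(standardized_euclidean(x, x), 0)
  expect_equal(standardized_euclidean(x, -x), 2)
  y <- c(1, 2, 3, 5)
  expect_equal(standardized_euclidean(x, y),
               sqrt(2 * (1 - pearson_oracle(x, y))), tolerance = 1e-12)
  ## affine invariance via standardization
  expect_equal(standardized_euclidean(3 * x + 7, -2 * y + 1),
               sqrt(2 * (1 + pearson_oracle(x, y))), tolerance = 1e-12)
  expect_equal(standardized_euclidean(x, y), standardized_euclidean(y, x))
  expect_error(standardized_euclidean(x, rep(1, 4)), "constant")
})

test_that("pairwise synchronization is zero for mirrored subjects and sqrt(2) for noise", {
  atlas <- synthetic_atlas(4)
  left <- make_block_ts(c(2, 2), T = 50, noise = 0.3, seed = 5)
  vals <- matrix(0, 8, 50)
  vals[c(1, 3, 5, 7), ] <- left
  vals[c(2, 4, 6, 8), ] <- left  # right hemisphere duplicates left
  expect_equal(unname(pairwise_synchronization(vals, atlas)), rep(0, 4))
  ## independent white-noise homologs: E[d^2] = 2, mean d near sqrt(2)
  atlas_big <- synthetic_atlas(200)
  noise <- withr::with_seed(21, matrix(rnorm(400 * 250), 400, 250))
  d <- pairwise_synchronization(noise, atlas_big)
  expect_equal(length(d), 200)
  expect_lt(abs(mean(d) - sqrt(2)), 0.02)
})

test_that("asymmetry indices are invariant to swapping pair members", {
  ## relabel hemispheres of every pair: rho and d must not change
  atlas <- synthetic_atlas(3)
  swapped <- as.data.frame(atlas)
  swapped$hemisphere <- rep(c("right", "left"), 3)
  swapped <- brainmark:::new_atlas(swapped)
  K <- random_K(6, seed = 13)
  ts <- make_block_ts(c(3, 3), T = 40, noise = 0.5, seed = 14)
  expect_equal(unname(global_connectivity_asymmetry(K, atlas)),
               unname(global_connectivity_asymmetry(K, swapped)),
               tolerance = 1e-12)
  expect_equal(unname(pairwise_synchronization(ts, atlas)),
               unname(pairwise_synchronization(ts, swapped)),
               tolerance = 1e-12)
})

test_that("the default atlas yields 45-dimensional asymmetry vectors", {
  atlas <- aal_atlas()
  vals <- withr::with_seed(31, matrix(rnorm(116 * 60), 116, 60))
  ts <- regional_ts(vals, "s1", atlas$name)
  K <- consensus_community_matrix(ts, community_config(k = 10, L = 5, seed = 2))
  a <- asymmetry_summary(ts, K, atlas)
  expect_equal(length(a$rho), 45)
  expect_equal(length(a$d), 45)
  expect_equal(a$pair_order, 1:45)
})
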