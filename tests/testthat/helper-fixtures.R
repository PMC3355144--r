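## Shared fixture builders. All randomness is seeded by the caller.

## P x T matrix with `sizes[b]` rows repeating block signal b plus noise
make_block_ts <- function(sizes, T = 40, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    sig <- matrix(stats::rnorm(length(sizes) * T), length(sizes), T)
    rows <- do.call(rbind, lapply(seq_along(sizes), function(b)
      sig[rep(b, sizes[b]), , drop = FALSE]))
    rows + noise * matrix(stats::rnorm(nrow(rows) * T), nrow(rows), T)
  })
}

## Independent Pearson correlation via the hand-expanded sum formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

## Random valid community matrix (symmetric, unit diagonal, [0,1])
random_K <- function(p, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(p * p), p, p)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
}

## Minimal precomputed-features object accepted by the classification schemes
fake_parts <- function(edges, rho, labels, ids = NULL) {
  n <- nrow(edges)
  p <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
  structure(list(edges = edges, crosscorr = edges, rho = rho, d = rho,
                 edge_index = edge_index(round(p)),
                 labels = as.integer(labels),
                 subject_ids = ids %||% paste0("s", seq_len(n)),
                 atlas = NULL, config = list()),
            class = "cohort_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Small strong-scenario cohort with planted links; shared by several tests
small_strong_cohort <- function(seed, n_per_group = 20, n_pairs = 12,
                                n_flipped = 5, timepoints = 120) {
  cfg <- synth_config("strong", n_controls = n_per_group,
                      n_patients = n_per_group,
                      atlas = synthetic_atlas(n_pairs),
                      timepoints = timepoints, n_blocks = 4,
                      n_flipped = n_flipped, seed = seed)
  generate_cohort(cfg)
}
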