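---
title: "Consensus community and asymmetry markers: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus community and asymmetry markers: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brainmark turns region-parcellated brain time series into two
functional-connectivity markers and runs them through a leakage-safe
classification protocol. This vignette explains the underlying models, the
parameters that matter, the synthetic cohort generator used for validation,
and the numerical decisions taken where more than one convention was
defensible. It states no empirical result; all numbers the package claims
are computed by its test suite and by `scripts/acceptance.R`.

## The consensus community matrix K

Functional connectivity is conventionally summarized by the cross-correlation
matrix of regional signals. That matrix is dense, and it does not expose
*community structure* — whether two regions act within the same functional
cluster. The community matrix takes a different route: treat the P regions as
points in T-dimensional time space, partition them with k-means under squared
Euclidean distance, record for every pair of regions whether they share a
cluster, and average this binary co-assignment over L independently
initialized runs. Entry K(i, j) is then the empirical probability that
regions i and j belong to the same functional community. With a deliberately
large k the matrix is sparse: only strongly cooperative regions co-cluster
reliably.

Tunable parameters, with defaults chosen for a 116-region, 250-timepoint
parcellation:

* `k = 30` clusters. Larger k sparsifies K; the consensus is empirically
  stable over a broad band of k (the package's `stability_sweep()` measures
  this as the Frobenius distance between K at each k and at a reference k,
  with the self-comparison at the reference k giving the pure Monte-Carlo
  floor).
* `L = 500` trials. Each K entry is a mean of L Bernoulli draws, so its
  standard error shrinks as 1/sqrt(L); the test suite checks this scaling at
  L = 10/40/160.
* `standardize_rows = TRUE`. Each region's series is z-scored before
  clustering, making the consensus invariant to per-region amplitude. Raw
  clustering is available (`FALSE`) for data whose amplitudes are meaningful.
* `cluster_scope = "all_regions"`. All atlas regions (cortex plus
  cerebellum) enter the clustering; downstream feature extraction restricts
  to the cortical submatrix. Cortical-only clustering is available by
  configuration, and for a 90-region cortical atlas both scopes coincide.

The Lloyd iteration is written out in the package rather than delegated,
because the consensus depends on exact deterministic conventions:
initialization samples k distinct data points without replacement; the
nearest-centroid assignment breaks ties by the lowest centroid index (which
guarantees identical rows always receive identical labels); a cluster
emptied during assignment is re-seeded with the point currently farthest
from its own centroid; convergence is an exact label fixed point, capped at
`max_iter = 300`. The farthest-point re-seeding matters for degenerate
inputs: on a zero-noise block fixture it guarantees that every block
eventually captures a centroid, so exact block structure is recovered for
any k at or above the block count — a property the test suite asserts.
`stats::kmeans` serves as an independent cross-check in the tests, never as
the implementation.

Trial seeds are derived from the configuration seed by a counter, so the L
trials are mutually independent yet the whole consensus is reproducible
bitwise.

## Hemispheric asymmetry: rho and d

For each of the 45 bilaterally homologous cortical region pairs the package
computes two complementary indices.

**Global connectivity asymmetry rho** compares how similarly the two members
of a pair connect to the rest of the cortex: `rho = 1 - cor(profile_i,
profile_j)`, where a region's connectivity profile is its row of K over the
other cortical regions. rho is 0 when the profiles are identical
(perfectly symmetric connectivity), 1 when unrelated and 2 when perfectly
anti-correlated.

Two conventions needed fixing:

* *Profile alignment.* Correlating two profiles only makes sense if position
  t refers to comparable targets in both. Under the default `mirrored`
  ordering the partner region comes first and, for every other pair, the
  opposite-hemisphere member precedes the same-hemisphere member; position t
  of region i's profile and position t of its homolog's profile then refer
  to mutually homologous targets. The inter-homolog entry K(i, j) itself is
  kept in both profiles (it is the leading element of each, and K(i, j) =
  K(j, i)). A `raw` atlas ordering is available by flag; the two differ only
  by a permutation applied to each profile.
* *Degenerate profiles.* A constant profile (a region co-clustering
  identically with everything, e.g. in an all-zero K) has no defined
  correlation; such pairs are returned as `NA` with a warning and excluded
  from group statistics rather than silently imputed.

**Pairwise synchronization d** compares the raw time series of the two
members directly, as a standardized Euclidean distance: both series are
z-scored (zero mean, unit population variance, removing baseline and
amplitude nonstationarity) and `d = sqrt(mean((zx - zy)^2))`. This
definition satisfies the exact identity `d = sqrt(2 * (1 - r))` with r the
Pearson correlation, bounding d in [0, 2] with sqrt(2) at independence. The
z-score-then-scale reading of "standardized Euclidean distance" was a
design choice; the identity it induces is asserted to 1e-12 in the tests,
and it makes d a monotone transform of homolog correlation, which matches
the intended interpretation of d as (inverse) interhemispheric
synchronization. Large d — weak synchronization — indicates stronger
asymmetry, concordant with large rho.

## Edge features and resampled sparse selection

The cortical submatrix of K is vectorized into its strict upper triangle in
row-major order — 90 regions give 4005 edge features per subject. With an
order of magnitude fewer subjects than features, edge selection precedes
classification. The package fits an L1-penalized linear regression of the
+1/-1 group labels on the column-standardized edges, but never as a single
fit: `sparse_select()` draws B class-stratified subject subsamples (fraction
`frac` each, without replacement), fits the lasso on each with the penalty
chosen by internal 5-fold cross-validation (`lambda.min`), and averages the
standardized coefficient magnitudes across subsamples. Edges are ranked by
this aggregate and the top `n_keep` are selected.

The resampling is the point, not a refinement: a single lasso fit thins out
groups of correlated discriminative edges to one representative, whereas
averaging across subsamples lets correlated edges take turns and keeps the
group. Defaults `B = 100`, `frac = 0.8`, mean-|coefficient| aggregation (a
selection-frequency aggregation is available by flag), `n_keep = 400`. The
coefficient magnitudes are rescaled to the standardized scale before
aggregation so that the ranking is invariant to column units; ties are
broken by canonical edge order.

Group-level edge statistics use the two-sided Wilcoxon rank-sum test (the
distribution of K edges is far from Gaussian) with Bonferroni correction.
Because most K edges are structurally zero, the correction uses an
*effective* comparison count: the number of entries of the grand-mean K
exceeding 0.05 (`nonzero_edge_count()`), not the full edge count. At a 0.05
family-wise level and 650 effective comparisons the per-edge threshold is
0.05/650 = 7.69e-5.

## Classification protocols and the leakage contract

`fit_predict()` wraps a support vector machine (linear kernel, C = 1 by
default; an RBF kernel is available). With thousands of features and
around a hundred subjects a linear decision function is the appropriate
default. Features are centered and scaled using training-fold statistics
only.

Three evaluation schemes share one contract — **every data-dependent step
(edge selection, standardization) is fitted inside the training portion
only**:

* `repeated_split_cv()`: class-stratified random 50/50 splits, selection and
  training on one half, prediction on the untouched half, aggregated over
  `repeats` (default 100).
* `loocv()`: leave-one-out, with selection re-fitted on the N-1 remaining
  subjects in every fold.
* `custom_split_eval()`: an explicit id-defined split, e.g. training on
  medicated patients plus controls and testing on unmedicated patients; the
  test set may be single-class.

Feature sets combine selected K edges, the 45-dimensional rho and d vectors,
and the cross-correlation baseline (`K_edges`, `rho`, `d`, `K_plus_rho`,
`crosscorr`, `K50_plus_rho`). Sensitivity counts patients (label -1) as the
positive class — a documented convention, as either polarity is defensible.
`edges_sweep()` repeats the split protocol over a grid of `n_keep` values.

The single most important test of this module is the *leakage detector*: on
null cohorts with no planted group difference, every scheme's accuracy must
sit inside the binomial 95% band around 0.5. Per-subject marker computation
(K, rho, d) is label-free and therefore computed once, outside the folds,
without violating the contract.

`single_link_rule_eval()` reproduces a closed-form contrast between
group-level significance and individual-level prediction: a link carried by
56 of 80 controls but 50 of 100 patients has a 20-point prevalence
difference, yet the rule "link present implies control" attains only
(28+25)/90 ≈ 59% expected accuracy on a proportion-preserving half split —
group differences do not automatically classify individuals.

## The synthetic cohort generator

No suitable public dataset pairs regional time series with the required
cohort structure, so validation rests on `generate_cohort()`, which emulates
the study conditions: 80 controls vs 100 patients, 116 regions, 250
timepoints by default, with full ground-truth bookkeeping. Its construction:

* Latent block signals: independent standardized AR(1) series (lag-1
  coefficient 0.3, approximating band-pass-filtered haemodynamic
  smoothness; 0 gives white noise for analytic checks). Region i's series is
  `coupling * s_block(i) + noise_sd * eps`.
* Planted community structure: homolog pairs are assigned to blocks; each
  planted discriminative link occupies its own two-pair block in controls,
  and in patients the second pair moves to a fresh block, flipping the
  link's co-membership between groups.
* Planted asymmetry: each right-hemisphere series mixes its left partner's
  latent signal with an independent one in variance-normalized ratio
  (1-a):a. a = 0 mirrors the hemispheres exactly (d = 0); a = 1 decouples
  them (d near sqrt(2)); group-mean rho and d are monotone in a, which the
  tests verify over a grid.

Scenario presets fix the effect parameters once: `strong` (coupling 0.9,
noise 0.4, 10 planted links, asymmetry 0.05 vs 0.45), `weak` (0.6, 0.9, 4
links, 0.1 vs 0.2) and `null` (no links, equal asymmetry — the leakage
condition). Explicitly passed arguments override presets so small test
atlases can scale the planted-link count down.

One consequence of mirrored hemispheres deserves emphasis: a planted link
between two bilateral pairs manifests in K as **four** statistically
exchangeable region-level edges (left-left, left-right, right-left,
right-right). The lasso distributes weight among them across resamples, so
recovery is assessed at the link level by default — a planted link counts as
found when any of its four realizations is selected
(`planted_edge_recovery()`, which also offers the strict single-column
reading). The ground truth records both the canonical left-left column and
all four realizations.

What the generator does *not* emulate: haemodynamic forward dynamics,
scanner and motion artifacts, spatially correlated noise, inter-subject
anatomical variability, or heterogeneous patient subtypes. Passing tests on
these cohorts therefore demonstrates the correctness and leakage-safety of
the pipeline and its statistical behavior under known ground truth — not
clinical-grade accuracy on real populations.

## Numerical choices and degenerate inputs

* Region order is atlas order everywhere; all matrices and vectors index
  regions in that single canonical order, and edge vectors use the row-major
  upper triangle. External files carry 0-based `region_id`s; R code indexes
  rows 1-based.
* Time series are stored raw; each operation standardizes internally as it
  requires (clustering optionally, d always, SVM on training folds).
* Constant region rows are rejected at load (they carry no connectivity
  information and would make d and profile correlations undefined).
* Matrix round-trips are written at full precision (17 significant digits)
  and re-validated on read (symmetry, [0, 1] range, unit diagonal).
* Labels are +1 (control) / -1 (patient) throughout, matching the
  regression encoding.
* Stratified resampling retries a degenerate single-class draw a bounded
  number of times, then errors; it cannot occur with per-class sampling but
  guards pathological inputs.
* All randomness flows from explicit seeds through a deterministic fan-out
  (seed plus stage/trial offsets, kept below 2^31), so identical
  configurations reproduce results byte for byte.

## Problem sizes used in the test suite

The validation suites run on scaled-down cohorts chosen to exercise the same
statistics at desk scale: consensus invariants on 50 random fixtures (P
around 8, L = 8); precision scaling at L = 10/40/160 with 25 replicates;
planted-link recovery on 20 cohorts of 90 subjects (44 regions, 120
timepoints, L = 40, B = 25); leakage detection on 20 null cohorts of 24
subjects under both split and leave-one-out protocols (B = 10); and a
strong-scenario end-to-end run with 40 subjects (24 regions, L = 50, 20
split repeats, B = 20). `scripts/acceptance.R` re-runs the strong-scenario
pipeline at the same 40-subject scale. The choices trade statistical
resolution against runtime on a single CPU; every threshold asserted is
derived from the construction (exact recovery, closed-form identities,
binomial bands) rather than fitted to observed outputs.

## Known limitations

* The consensus is a Monte-Carlo estimate; at small L the sampling floor
  dominates comparisons between matrices (quantified by `stability_sweep()`).
* k-means with squared Euclidean distance on z-scored series is equivalent
  to clustering by correlation pattern; signals coupled nonlinearly or with
  time lags are invisible to it, as they are to the cross-correlation
  baseline.
* rho requires non-degenerate profiles; cohorts with empty community
  matrices (e.g. k equal to P) produce NA pairs by design.
* The lasso's internal cross-validation chooses the penalty per subsample;
  with very few subjects per class the choice is noisy, which the resample
  aggregation dampens but does not remove.
* Classification reports quantify performance under the generator's
  assumptions; transfer to real cohorts requires real validation data.
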