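Package: brainmark
Title: Consensus Community and Hemispheric Asymmetry Markers for Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two functional-connectivity markers from region-parcellated
    brain time series: a consensus k-means community matrix K (the empirical
    probability that two regions fall in the same functional cluster across
    repeated clustering runs) and hemispheric asymmetry indices over bilaterally
    homologous region pairs (global connectivity asymmetry rho and pairwise
    synchronization d). Provides resampled L1-regression edge selection,
    rank-sum and t-test group statistics, nested support-vector-machine
    cross-validation protocols (repeated split, leave-one-out, custom splits),
    a synthetic two-group cohort simulator with planted community structure and
    planted asymmetry, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
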