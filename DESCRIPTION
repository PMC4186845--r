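Package: boldvar
Title: Resting-State BOLD Signal Variability, Seed-Based Connectivity and
    Monte-Carlo Cluster Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating resting-state functional MRI measures to
    behavioural performance across subjects. Implements per-subject
    preprocessing of 4D BOLD time series (spatial smoothing, initial-volume
    discard, 19-regressor nuisance regression with mean restoration,
    percent-signal-change conversion, run concatenation, framewise
    displacement), voxelwise BOLD signal variability mapping, seed-based
    functional connectivity with Fisher z-transformation, across-subject
    correlation of either metric with a behavioural score, and Monte-Carlo
    cluster-extent familywise-error correction with anatomically labelled
    cluster reports. A seeded synthetic-cohort generator produces
    multi-subject 4D datasets with AR(1) temporal noise, Gaussian spatial
    smoothness, region-specific variability-score effects and seed-target
    connectivity coupling, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
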