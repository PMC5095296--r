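Package: orthospace
Title: Orthogonal Preparatory and Movement Subspaces in Neural Population Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-level analysis of motor-cortex activity around a delayed
    reach: preprocessing of trial-averaged firing rates (Gaussian smoothing,
    soft-normalization, cross-condition mean-centering), pairwise cross-condition
    correlation structure and the epoch-preference index with a dip test for
    bimodality, the PCA alignment index with a covariance-matched random-subspace
    Monte Carlo null, simultaneous identification of mutually orthogonal
    preparatory and movement subspaces by normalized trace maximization, and the
    linear mapping linking late-preparatory to mid-movement population states with
    leave-one-out cross-validation and a condition-shuffle null. Includes a gated
    feed-forward latent dynamical model as a synthetic-data generator with known
    ground-truth subspaces, so the full pipeline can be exercised and calibrated
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
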