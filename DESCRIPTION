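Package: specklestress
Title: Laser Speckle Imaging Coefficients and Hypoxic-Stress Classification for Stored Fruit
Version: 0.1.0
Authors@R: person("specklestress", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Computes dynamic laser speckle activity coefficients from grayscale
    speckle video stacks (stretched-exponential decorrelation relaxation time,
    temporal laser speckle contrast, and the gray-level co-occurrence inertia
    moment of time-history speckle patterns), simulates dynamic speckle videos
    with known ground-truth field dynamics via temporally correlated complex
    Gaussian fields, assembles per-fruit multi-signal stress time courses with a
    two-of-three expert labeling rule, and trains gradient-boosted decision-tree
    classifiers of hypoxic stress over twelve predictor-set variants with
    repeated 70/30 validation and gain-based feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
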