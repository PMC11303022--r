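Package: gazebias
Title: Preferential-Looking Eye-Tracking Analysis with Bayesian Zero-One-Inflated Beta Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing two-stimulus preferential-looking
    eye-tracking experiments on emotional attention biases. Provides a
    seeded synthetic-gaze generator, velocity-threshold fixation detection,
    k-means calibration-drift estimation and correction, per-trial region
    of interest metrics (total fixation duration, time to first fixation),
    the validity filters and looking statistics of the paradigm
    (proportional looking duration with attention weights, first-fixation
    location), and from-scratch Bayesian inference via adaptive
    Metropolis-within-Gibbs for weighted zero-one-inflated beta and
    logistic mixed regressions, with highest-density intervals,
    probability of direction and Gelman-Rubin diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
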