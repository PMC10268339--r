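Package: batmotus
Title: Fall Migration, Over-Water Flight, and Residency Activity of Coastal
    Bats from Automated Radio Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for Motus-style automated radio-telemetry
    detections of migratory tree bats. Cleans raw detection tables (run-length,
    implausible-distance, and tag-drop filters), classifies individuals into
    movement categories (site resident, migrant, long-distance-return) with
    circular bearing summaries, detects same-night over-water crossings of
    labeled water bodies and fits a use-availability resource-selection model
    (random-intercept logistic regression by adaptive Gauss-Hermite
    quadrature, all-subsets AICc selection, marginal effects), and fits
    per-individual two-state hidden Markov models of hourly signal-strength
    variability whose transition probabilities depend on cyclical
    time-of-night covariates (EM with forward-backward, Viterbi decoding).
    A seeded synthetic-data generator emulates tower networks, hourly
    weather, and bat trajectories with ground-truth labels so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    lme4,
    knitr,
    ggplot2
Config/testthat/edition: 3
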