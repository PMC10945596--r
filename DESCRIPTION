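Package: rhythmnest
Title: Hierarchical Rhythm Analysis of Vocal Pulse Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting isochrony and nested (self-embedded) rhythmic
    structure in annotated animal vocal sequences, built around inter-onset
    intervals and their rhythm ratios. Reads Raven-style selection tables,
    computes interval ratios with on/off-isochrony band classification and
    kernel-density peak extraction, quantifies cross-stratum tempo nesting
    (sub-pulse versus enclosing pulse), tests band preference with a
    negative-binomial count model using a band-width offset and per-individual
    effects, and runs a crossed permuted discriminant function analysis of
    acoustic features. Includes a synthetic generator of two-stratum pulse
    trains so every stage of the pipeline can be exercised without field
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    withr,
    MASS,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
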