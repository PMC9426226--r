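Package: irrsim
Title: Simulation-Based Evaluation of Interrater Reliability Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing chance-corrected interrater reliability
    indices (percent agreement, Bennett's S, Perreault and Leigh's Ir,
    Gwet's AC1, Scott's pi, Cohen's kappa, Krippendorff's alpha) against
    observed "golden standard" reliability and chance agreement. Includes a
    Monte Carlo generator of truth-labeled two-rater rating sessions with
    involuntary, difficulty-dependent guessing confined to two confusable
    categories; golden-standard observation of right/erroneous agreement,
    true chance agreement and true reliability; predictive-accuracy metrics
    (directional r squared, mean of errors, error of means) with benchmark
    verdicts; and a full factorial category-by-difficulty-by-skew
    experiment pipeline with reportable factor-effect and cell-mean tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
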