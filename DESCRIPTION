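Package: periens
Title: Peri-Event Neural Ensemble Analysis and Population Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-aligned calcium-imaging and fiber-photometry
    recordings from behaving animals. Provides delta-F/F and z-score normalisation,
    peri-event epoch extraction, permutation-based detection of event-activated
    neurons, selectivity-response-index classification across two events,
    pre-/post-phase cell phenotyping, linear population decoding with
    cross-validation and shuffled-label nulls (including hyperplane-projection
    decoding of continuous sessions and peri-onset decoding time courses),
    photometry onset-latency metrics, and conditioned-place-preference scores.
    Includes a synthetic session generator with known ground truth so every stage
    is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    data.table,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
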