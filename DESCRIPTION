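Package: screenstop
Title: Simulation of Stopping Rules for Active-Learning Screening in
    Systematic Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates technology-assisted title-and-abstract screening
    for systematic reviews (an iteratively retrained TF-IDF naive-Bayes
    ranker over a labeled citation corpus) and evaluates three early
    stopping rules retrospectively on each screening trajectory: stopping
    at an extrapolated count of relevant records, stopping after a run of
    consecutive irrelevant records, and stopping at a fixed fraction of
    the dataset. Includes a synthetic labeled-corpus generator with
    tunable class separability and prevalence, delimited-text and RIS
    corpus I/O, per-trajectory safety and work-saved metrics, and a
    seeded replicate-grid orchestrator with plain-text report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
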