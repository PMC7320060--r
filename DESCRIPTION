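Package: walkmem
Title: Spatiotemporal Context Effects on Recognition Memory in Walked
    Virtual Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for old/new recognition experiments in which
    items are encoded while physically walking a tracked virtual environment.
    Reads and validates 10 Hz position/heading trajectory logs, attributes
    helmet gaze to wall items, extracts visits, viewing times and travelled
    spatial/temporal distance matrices, builds the 77-trial recognition
    sequence with sequential-pair reordering, computes boundary (same- vs
    across-room) and ordinal-lag conditional hit rates, source attribution,
    signal-detection indices and confidence summaries, and estimates
    distance-based mnemonic probability functions (d-MPFs) tested with a
    sign-flip permutation t-test. Includes self-contained JZS Bayes factors
    and noncentral-t power, and a generative synthetic-cohort simulator with
    injectable boundary, lag and distance effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
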