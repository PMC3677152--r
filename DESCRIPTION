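Package: ipmsdiff
Title: Bait-Normalized Differential Analysis of Label-Free IP-MS Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential interaction analysis for label-free
    immunoprecipitation mass spectrometry (IP-MS / AP-MS) experiments.
    Implements the peptide-to-protein intensity rollup over unique peptide
    ions, per-run bait normalization, a replicate-presence filter, group
    fold changes with unpaired t-tests, and conjunctive hit calling
    (minimum quantified peptides, fold-change bound, significance bound).
    Includes a seeded synthetic-data generator for replicate IP-MS designs
    with known differential structure, and small helpers for western-blot
    densitometry, quantitative FISH, and dual-luciferase reporter
    statistics. All user-facing functions take and return tibbles so
    pipeline stages chain with the pipe.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    withr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
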