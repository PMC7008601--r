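Package: antigenscreen
Title: Candidate Autoantibody Screening from Immunoprecipitation Mass
    Spectrometry Presence-Absence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate autoantibody biomarkers from
    immunoprecipitation shotgun mass-spectrometry identification tables,
    as used in cerebrospinal-fluid antigen screens. Reads per-sample
    peptide/protein identification tables (long TSV or wide
    presence-mark dialects), merges technical replicates, builds a
    protein-by-sample presence matrix with unique-peptide statistics,
    removes abundant serum proteins with an editable blocklist, applies
    a two-part group-frequency selection rule (near-absence in controls,
    detection in at least half the patients), and reports candidates,
    group overlaps, positive-control QC and cohort demographic
    statistics. A seeded synthetic-study generator makes every stage
    testable, including the selection rule's operating characteristics
    against exact binomial expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
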