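Package: jiaassoc
Title: Clinical-Parameter Transcript Association Analysis for Juvenile
    Idiopathic Arthritis Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for kinetic-PCR gene panels profiled in
    systemic (SJIA) and polyarticular (POLY) juvenile idiopathic
    arthritis cohorts. Normalizes raw assays against housekeeping genes,
    scores samples with clinical flare/quiescence rules (systemic and
    arthritis severity scores, ESR partition, SAF/AF subgroups),
    identifies erythrocyte-sedimentation-rate and joint-count associated
    transcripts by a dual-track (Pearson correlation and Student t-test)
    procedure gated by permutation-based global and local false
    discovery rates, scores canonical-pathway gene sets by
    hypergeometric over-representation, and compares pathway profiles
    between clinical conditions against a permutation-derived
    significance threshold. Includes a synthetic-cohort generator with
    planted effects so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
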