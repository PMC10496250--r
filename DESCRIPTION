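Package: efminer
Title: Rule-Based Mining of Ejection Fraction from Clinical Text and
    Heart-Failure Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts quantitative left-ventricular ejection fraction (EF)
    readings from unstructured clinical notes with a rule-based,
    regular-expression mining algorithm (numeric, range and worded EF
    expressions, with date-masquerade and past-reading quality checks),
    consolidates them into per-patient per-date measurements, combines them
    with structured NT-proBNP and creatinine laboratory data to classify
    patients into heart-failure subtypes (HFrEF, HFmrEF, HFpEF, no HF),
    validates classifications against a gold standard with confusion-matrix
    diagnostics, and fits age-scale Cox proportional-hazards models of
    mortality by subtype. Includes a seeded synthetic-EHR generator with
    machine-readable ground truth so the full pipeline is testable without
    access-restricted patient data.
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
    stringr,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
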