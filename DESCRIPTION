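Package: methylscreen
Title: Integrative CRISPR Dependency and Methylation Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for nominating DNA-methylation biomarkers of
    drug sensitivity and genetic dependency in cancer cell line cohorts.
    Covers pooled CRISPR screen beta-score dependency estimation with
    control anchoring, age-group differential dependency testing,
    four-parameter logistic dose-response fitting with IC50/AUC sensitivity
    classification, cross-validated random-forest biomarker nomination with
    ranked-importance normalization, correlation-based CpG cluster
    discovery with Fisher-exact binarization-cutoff scanning, and a
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    ranger,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
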