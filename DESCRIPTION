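Package: ferroscore
Title: Ferroptosis Gene-Signature Scoring for Kidney Transplant Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus clustering of transplant-biopsy expression profiles
    restricted to a ferroptosis gene panel, derivation of up/down gene
    signatures by empirical-Bayes moderated differential expression, a
    PCA-based per-sample ferroptosis score with rotation-based projection
    onto external cohorts, and diagnostic (ROC/AUC, Youden cutoff) and
    prognostic (Kaplan-Meier, log-rank, fixed-horizon ROC) evaluation.
    Includes a synthetic two-phenotype cohort generator with planted
    driver/suppressor shifts and score-linked survival, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
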