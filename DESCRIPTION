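Package: lungmetab
Title: Plasma NMR Metabolomic Discrimination of Lung Cancer from
    PET-Positive Lung Inflammation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating lung cancer from benign PET-positive
    lung inflammation using plasma 1H-NMR integration-region profiles.
    Implements PLS-LDA classification with nested LASSO top-K feature
    selection, balanced repeated four-fold cross-validation with feature
    stability accounting, ablation and per-stage leave-one-out analyses,
    Welch/Benjamini-Hochberg univariate screening with volcano
    classification, ROC construction with Youden cutoff derivation,
    empirical and binormal AUC, diagnostic-metric arithmetic from counts
    or printed rates, and a combined SUVmax/glutamate decision rule with
    discordance accounting. Includes a synthetic cohort generator that
    emulates published group structure and marker distributions so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
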