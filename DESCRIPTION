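Package: qsarnest
Title: Nested Cross-Validated QSAR Regression with Applicability-Domain-Gated
    Consensus Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    regression models for compound potency (pIC50) from binary structural
    fingerprints or continuous molecular descriptor tables.  Covers the full
    modelling workflow: activity-table curation (structure standardization,
    salt stripping, duplicate merging by median IC50, train/test splitting),
    MACCS fingerprint computation, variance and correlation preprocessing
    filters, information-theoretic (CMIM/JMIM), Boruta and genetic-algorithm
    feature selection, nested cross-validation with replicate seeds,
    y-randomization with the Rp-squared validity statistic, stacked
    ensembling of out-of-fold predictions, similarity- and isolation-forest
    applicability domains, and applicability-domain-gated consensus virtual
    screening.  Ships a synthetic-data generator emulating the statistical
    structure of fingerprint and descriptor datasets so the whole pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
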