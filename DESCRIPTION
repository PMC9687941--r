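Package: pharmacorank
Title: Protein Drug-Target Prioritization and Drug Repositioning by
    Shared-Function Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes the proteins associated with a disease by how
    frequently their functional annotations (UniProt keywords, Gene Ontology
    terms, EC numbers, InterPro assignments, and related vocabularies) are
    shared within the disease's protein set, calibrates the resulting
    priority scores against the fraction of proteins targeted by medications
    already indicated for the disease (the pertinency score) using an
    inverse-variance weighted quadratic fit over cross-validation folds, and
    emits ranked drug-repositioning candidates with predicted pertinency
    scores and an empirically derived decision threshold. Includes ROC/AUC
    validation with annotation-type ablation, a two-snapshot indication
    comparison for threshold estimation, and a synthetic-data generator so
    the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
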