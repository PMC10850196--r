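Package: pvlabel
Title: Predicting Drug Package-Insert Safety Label Changes from Spontaneous
    Adverse Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance label-change prediction from a
    spontaneous adverse-drug-reaction reporting database. Builds labeled
    drug-reaction cohorts from a package-insert revision log, computes
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio, Yates-corrected chi-squared) and a 34-feature summary
    of each drug-reaction pair's reporting history, and trains and
    benchmarks binary classifiers (RBF-kernel support vector machines and
    gradient boosting) that predict whether a clinically significant
    adverse reaction will be added to the drug's package insert. Includes
    a synthetic report-database simulator with planted signals so the full
    pipeline can be validated against known ground truth, and the
    conventional signal-detection rule (n >= 3, chi-squared >= 4, PRR >= 2)
    for comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    ranger,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
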