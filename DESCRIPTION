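Package: seldiflow
Title: Serum SELDI-TOF MS Biomarker Discovery Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible re-implementation of a serum SELDI-TOF mass
    spectrometry biomarker-discovery workflow: synthetic spectrum cohorts
    with known ground truth, baseline subtraction and total-ion-current
    normalization with outlier-spectrum removal, first-derivative peak
    detection with a local median + 5*MAD noise filter, cross-sample peak
    alignment by one-dimensional complete-linkage clustering, Wilcoxon
    rank-sum peak ranking, weighted least-squares support vector machine
    classification with leave-one-out validation, ROC/AUC reporting, and
    Shewhart/Westgard laboratory quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
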