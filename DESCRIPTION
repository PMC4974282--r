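Package: dmscreen
Title: Combined FDG-PET/CT Interpretation and Diagnostic Accuracy for Distant-Metastasis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating screening strategies for distant metastases
    in head and neck squamous cell carcinoma patients with high-risk factors.
    Implements a decision rule that combines paired whole-body FDG-PET and
    contrast-enhanced chest CT readings into a single positive/negative call
    (PET positivity dominates; CT-detected pulmonary lesions below the 5-mm
    PET detection limit are called on CT alone), a follow-up-based reference
    standard with exclusion and locoregional-control stratification rules,
    diagnostic accuracy statistics with exact Clopper-Pearson confidence
    intervals, ROC analysis over five-point ordinal reader scores with paired
    placement-value (DeLong) inference, a deterministic reconstruction of a
    published 47-patient validation cohort, and a configurable cohort
    simulator for property-based testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
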