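Package: ipmncea
Title: Cost-Effectiveness of Supplemental FDG-PET/CT for Detecting Malignant
    Transformation of IPMN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-tree plus Markov cohort state-transition modelling of two
    diagnostic strategies for intraductal papillary mucinous neoplasms (IPMN)
    under evaluation for malignant transformation: conventional cross-sectional
    imaging (CT/MRI) versus CT/MRI with a supplemental FDG-PET/CT examination.
    The package provides validated parameter handling for the literature-derived
    inputs (test accuracies, costs, utilities, transition probabilities and
    economic settings), age-adjusted background mortality from life tables,
    an annual-cycle cohort engine with discounted cost and QALY accumulation,
    incremental cost-effectiveness and net-monetary-benefit analysis,
    deterministic one-way sensitivity (tornado) and threshold analysis, a
    structural-variant calibration harness, and an individual-level
    microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
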