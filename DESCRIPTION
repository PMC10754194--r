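Package: sofaoxi
Title: SpO2-Based Respiratory SOFA Scoring and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the respiratory Sequential Organ Failure Assessment
    (SOFA) sub-score under seven strategies for handling missing arterial
    oxygen tension (PaO2): conventional normal-value imputation and six
    pulse-oximetry (SpO2) based estimation methods, together with total
    six-organ SOFA scoring. Provides the evaluation machinery used to
    compare such strategies against in-hospital mortality (midrank AUROC
    with DeLong variance and paired tests, exact binomial per-score
    mortality, bootstrap calibration curves), a synthetic emergency
    department infection cohort generator with severity-dependent PaO2
    missingness, and a reproducible simulate-score-evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
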