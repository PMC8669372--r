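Package: pcoscreen
Title: Fuzzy Multi-Criteria Screening for PCOS and Associated Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Questionnaire-based screening for polycystic ovarian syndrome
    (PCOS) and associated mental-health issues. A 31-item instrument (physical
    symptoms, the Kessler K10 distress items, social phobia, body-image
    dissatisfaction) is mapped to one of four diagnostic categories by fuzzy
    multi-criteria decision analysis: criterion weights are derived by fuzzy
    AHP (triangular-fuzzy pairwise comparisons, geometric-mean weights,
    centre-of-area defuzzification), each of two channels (physical, mental)
    ranks three severity levels by fuzzy TOPSIS closeness coefficients, and a
    nine-rule fuzzy rule base fuses the two channel levels into a final
    category. Also provides the comparison machine-learning baselines
    (stratified split, nearest-neighbour mean oversampling, SVM/KNN/decision
    tree), confusion-matrix metrics with per-class TP/FP/FN/TN, cohort-level
    wellness indicators, and a synthetic-cohort generator with controllable
    class separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    e1071,
    class,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
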