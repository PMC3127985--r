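Package: comorbibench
Title: Comparative Validation of Claims-Based Comorbidity Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds population-based cohorts from linked administrative
    health claims (hospital discharge abstracts, physician billing claims,
    outpatient drug dispensations, population registry, vital statistics),
    computes five comorbidity measures over a one-year assessment window
    (distinct-diagnosis count, Charlson index, the 31 Elixhauser condition
    indicators, distinct drug-class count, and the Chronic Disease Score),
    and compares their ability to predict one-year death and hospitalization
    with logistic models evaluated by the c-statistic (DeLong confidence
    intervals and paired tests), Brier score, and Hosmer-Lemeshow test.
    A synthetic claims generator with known outcome-generating models makes
    the whole pipeline testable without access to real registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
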