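Package: adheretrack
Title: Medication Adherence (Proportion of Days Covered) and Activity-Tracking Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for claims-based medication adherence research: construction of
    condition cohorts from diagnosis codes and pharmacy fills, proportion-of-days-covered
    (PDC) computation under fixed and variable denominator methodologies with
    supply-period carryover and refill stockpiling, wearable activity-tracking metrics
    including an empirical-Bayes adjusted tracking ratio, and logistic-regression
    association models between adherent status and tracking behaviour. Includes a
    synthetic claims/activity data generator with known ground truth for validation
    and an end-to-end pipeline producing summary and odds-ratio tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
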