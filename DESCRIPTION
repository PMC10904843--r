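Package: raredetect
Title: Rule-Based EHR Screening for Undiagnosed Rare-Disease Suspects
Version: 0.1.0
Authors@R: person("OIA", "Analytics", email = "analytics@example.org",
    role = c("aut", "cre"))
Description: Flags suspected undiagnosed cases of Fabry disease and familial
    hypercholesterolaemia (FH) from structured electronic-health-record
    tables (patients, problem lists, laboratory results, medication orders).
    Fabry suspects are patients under 50 years old with phenotypes in at
    least two of five organ systems; FH suspects have premature
    atherosclerotic cardiovascular disease or severely elevated LDL
    cholesterol, including statin-adherence-conditioned thresholds.
    Clinical concepts are matched through value sets that unify coding and
    spelling variants. Includes cohort analytics (system-interaction and
    Venn-region counts, demographics, Welch/pooled two-sample t-tests,
    prevalence arithmetic), a synthetic structured-EHR cohort generator
    with a ground-truth manifest for end-to-end validation, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
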