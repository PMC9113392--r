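Package: pedtriage
Title: Five-Level Pediatric Emergency Triage Rules and Diagnostic-Accuracy
    Validation Against the Pediatric Early Warning Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a configurable five-level pediatric emergency
    department triage decision rule (critical-condition shortcut,
    max-severity aggregation over complaint items, moderation by
    out-of-range vital signs and risk conditions, upgrade-only nurse
    override, fractile response-time targets) together with a Pediatric
    Early Warning Score (PEWS) calculator, and the diagnostic-accuracy
    machinery to validate the triage rule against PEWS as reference
    standard: 2x5 cross-tabulation, dichotomization into high- vs
    low-level emergencies, sensitivity/specificity/predictive values with
    Wilson score intervals, likelihood ratios with log-method intervals,
    agreement and over-/under-triage proportions, stratified subgroup
    reports, outcome rates and length-of-stay ANOVA with Scheffe post hoc
    contrasts. A synthetic-cohort generator emulates a large validation
    cohort so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
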