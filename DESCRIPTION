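Package: deprescr
Title: Patient-Level Cost-Utility Microsimulation of Antihypertensive
    Deprescribing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov patient-level microsimulation comparing withdrawal of
    one antihypertensive medication against usual care in adults aged 80
    and over, from a UK NHS/PSS perspective. Simulated patients face
    per-cycle risks of cardiovascular events, drug-related adverse events
    and life-table mortality over a 20-year horizon; a sustained systolic
    blood-pressure difference between arms is translated into event
    relative risks by log-linear interpolation, and survivors of serious
    events carry standardised mortality ratios. Provides synthetic cohort
    generation calibrated to deprescribing-trial baseline characteristics,
    discounted cost and QALY accrual with half-cycle correction,
    incremental cost-effectiveness ratios, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, bisection
    threshold analysis, and deterministic scenario and subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
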