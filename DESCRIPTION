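Package: ckdsim
Title: Patient-Level Microsimulation of Chronic Kidney Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete-time Monte Carlo microsimulation of chronic kidney
    disease (CKD) at the individual level. Synthesises virtual national
    cohorts from demographic pyramids and KDIGO G x A stage distributions,
    advances them through annual cycles (eGFR slope progression, albuminuria
    transitions, incident CKD, diagnosis, cardiovascular events, kidney
    replacement therapy and all-cause mortality driven by KDIGO risk-grid
    relative risks), calibrates kidney replacement therapy prevalence by
    regression extrapolation, and aggregates outputs into per-100,000
    prevalences, cumulative incidences, percent changes and population-
    weighted cross-country summaries, including diagnosis-rate sensitivity
    scenarios under common random numbers. Ships a synthetic country-input
    generator with known ground truth and transcribed cross-country
    reference tables for rollup verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
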