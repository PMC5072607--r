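Package: chant
Title: Development and Validation of a Four-Item Clinical Neuropathy Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for developing and validating brief clinical screening
    instruments for distal symmetrical polyneuropathy, built around a four-item
    bilateral screen (feet pain, feet numbness, great-toe vibration, ankle
    reflexes) for HIV-associated sensory neuropathy. Provides orientation-aware
    empirical ROC analysis with four cutoff-selection criteria and their
    geometric-mean consensus, weighted misdiagnosis cost curves, partial
    eta-squared effect sizes, composite reference standards (2-of-3 deep
    phenotype case definition and a symmetric examination-score proxy), the
    combination decision rule with its scoring rubric and an exhaustive
    monotone-rule alpha test, neuropathic-pain triage from a pain interview and
    body map, and a validation suite (2x2 accuracy metrics, likelihood ratios,
    post-test probability, Cronbach alpha, item-total and inter-tester rank
    correlations, content validity ratio). A seeded synthetic-cohort generator
    with calibrated per-item accuracy makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
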