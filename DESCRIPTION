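Package: pdcmsm
Title: Medication Adherence from Prescription Records and Marginal
    Structural Models of LDL-Cholesterol Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pharmacoepidemiological analysis of statin
    adherence and LDL-cholesterol response from primary-care style
    prescription and biomarker logs. Computes proportion-of-days-covered
    (PDC) adherence from dispensing events, including first-year window
    rules and interval PDC between follow-up visits; derives LDL-c change
    ratios and per-visit reduction trajectories with configurable validity
    filters; and estimates the causal effect of sustained adherence on
    LDL-c reduction with inverse-probability-of-treatment weighting for
    continuous sequential exposures, using covariate-balancing
    (entropy-tilted) stabilized weights, weighted correlation balance
    diagnostics, weighted least squares, and intervention contrasts. A
    synthetic cohort generator with known ground truth emulates the causal
    structure of adherence feedback and time-varying confounding so every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
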