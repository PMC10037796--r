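Package: gendermech
Title: Gendered Mechanisms Behind Sex Differences in Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation and interaction analysis of sex differences in
    allostatic-load biomarkers (systolic blood pressure, triglycerides, LDL
    cholesterol, HbA1c, CRP, cortisol). Implements gender-diagnosis scoring
    (predicted probability of being male-born from socio-behavioural
    characteristics), g-computation of total effects, controlled direct
    effects with the gender score or the full mediator set fixed, eliminated
    proportions, and additive sex-by-early-deprivation interaction, with
    bootstrap-then-impute percentile confidence intervals (single stochastic
    chained-equation imputation inside each bootstrap replicate). A synthetic
    birth-cohort generator with closed-form true estimands supports testing
    and calibration without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
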