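Package: stovesim
Title: Design, Simulation and Analysis of Stepped-Wedge Cookstove Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing community-randomized cookstove
    trials with a stepped-wedge rollout. Provides the trial design container and
    randomization procedures (wedge-order draw, stratified household
    randomization); a generative simulator for child respiratory-outcome panels
    under a logistic mixed model with village and child random intercepts,
    seasonality and secular trend; rule-based detection of acute lower
    respiratory infection (ALRI) episodes from daily symptom diaries with
    severity grading; signal-processing of 10-second household air-quality
    logger traces into stove-influenced time (SIT) and integrated excess
    concentration (SIP/SIC) summaries; maximum-likelihood fitting of the
    analysis model with natural-spline time adjustment, cluster-robust variance
    estimation and spline-sensitivity analysis; and simulation-based power
    studies plus closed-form design-effect sample-size calculators for
    clustered birthweight outcomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    lme4,
    glmmTMB,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
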