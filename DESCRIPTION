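Package: ventdose
Title: Minute Ventilation Prediction from Heart and Breathing Rate and
    Inhaled Dose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates minute ventilation normalized by forced vital capacity
    (VE/FVC) from heart rate and breathing rate, the full processing chain
    from 1-second physiologic records and breath-by-breath tidal volumes to
    time-averaged analysis datasets, random-intercept linear mixed models fit
    by restricted maximum likelihood, brute-force all-subsets model selection
    with subject-grouped five-fold cross-validation and percent-error scoring,
    NHANES III spirometry reference equations, and downstream time-resolved
    inhaled-dose estimation for air pollutants such as PM2.5. Includes a
    synthetic-data generator that emulates a treadmill exercise protocol and
    field exposure sessions under a known ground-truth ventilation model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
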