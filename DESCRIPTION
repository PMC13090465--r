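Package: scalenorm
Title: IRT Calibration, Measurement-Property Evaluation and Normative
    References for Child Mental-Health Screening Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric validation pipeline for ordinal screening
    questionnaires: per-subscale graded response / graded rating scale
    model calibration by marginal maximum likelihood, expected a
    posteriori trait scores, test information, infit statistics and
    summed-score posteriors (Lord-Wingersky recursion);
    limited-information global fit (M2-type statistic with RMSEA, CFI,
    TLI and SRMR), residual correlations, Mokken scalability and
    monotonicity checks, Cronbach's alpha and McDonald's omega-total;
    a COSMIN-style pass/fail rubric over these statistics; and local
    normative reference tables mapping crude summed scores to Z, T,
    percentile and PROMIS severity bands by age group and gender.
    Ships machine-readable structures for six instruments (PSC-17,
    RCADS-25, SNAP-IV, MCHAT-R/F, CAST, CATS-2) and a synthetic-cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
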