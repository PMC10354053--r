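Package: msjoint
Title: Joint Longitudinal-Survival Modelling of Genetic Prognostic Indices
    in Relapse-Onset Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage estimation of indirect, time-dynamic associations
    between multiple sclerosis relapses and disability worsening via
    longitudinal genetic prognostic indices embedded in Bayesian joint
    longitudinal-survival models. Provides counting-process construction of
    worsening/improvement transitions from EDSS visit records, penalized Cox
    variant selection and mixed-effects Cox fitting of time- and
    latitude-interacting SNP effects, a Bayesian natural-cubic-spline
    trajectory model, constant- and varying-coefficient joint models with
    P-spline baseline hazards, dynamic individual survival prediction with
    time-dependent AUC and prediction error, and a seeded synthetic-cohort
    generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    MASS,
    pracma,
    stats,
    survival,
    utils,
    yaml
Suggests:
    splines,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
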