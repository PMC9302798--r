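Package: liferisk
Title: Lifetime Risk and Life Years with Diabetes from Longitudinal
    Glycemic Surveillance Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the remaining lifetime risk of diabetes
    and the expected life years lived with and without diabetes from
    longitudinal glycemic surveillance records. Raw opportunistic
    measurements (fasting plasma glucose, HbA1c, 2-hour OGTT) and clinical
    flags are classified into normoglycemia, prediabetes and diabetes
    person-time using American Diabetes Association thresholds; age- and
    sex-specific one-year transition probabilities of a four-state
    illness-death Markov chain are estimated by a discrete-time
    occurrence/exposure estimator; lifetime risk and life years are computed
    by Monte Carlo cohort simulation and cross-validated by a modified
    Kaplan-Meier estimator with age as the timescale, a Sullivan life table,
    and age-period-cohort spline extrapolation of birth-cohort rates. A
    synthetic registry generator with known ground-truth transition
    intensities emulates an electronic-medical-record surveillance database
    so that every stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    splines,
    stats,
    utils,
    yaml
Suggests:
    cmprsk,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
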