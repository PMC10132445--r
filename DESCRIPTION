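Package: agemort
Title: Age-Structured Overdose Mortality Modelling and Ensemble Kalman Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic (method-of-characteristics) solutions of an age-structured
    mortality model for populations with substance use disorder, including a
    gamma-mixture age-dependent addiction influx and cumulative overdose death
    accounting. Provides a perturbed-observation ensemble Kalman filter with
    state augmentation for joint estimation of the population density and the
    model parameters from age-binned annual death counts, twin-experiment
    synthetic data generators, readers and writers for CDC WONDER style
    tab-delimited mortality exports, and reproducible command-style entry
    points for parameter estimation and short-term mortality forecasting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
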