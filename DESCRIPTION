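Package: ttcjm
Title: Joint Longitudinal-Survival Models for Drug Trough Concentration
    Exposure-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying exposure-response relationships between
    longitudinal plasma trough concentrations of oral targeted anticancer
    agents and progression-free survival. Raw plasma samples are
    extrapolated to trough concentrations and normalized through a sigmoid
    Emax transformation; the resulting transformed trough concentrations
    (TTC) are analysed with standard and time-dependent Cox proportional
    hazards models and with a Bayesian joint model linking a linear
    mixed-effects trajectory to the hazard through current-value,
    average-exposure, or combined association structures. Includes a
    synthetic cohort generator with known ground truth for validating the
    full pipeline, WAIC and LPML model comparison, and Kaplan-Meier
    summaries including reverse Kaplan-Meier follow-up estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
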