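Package: mgborrow
Title: Bayesian Borrowing and Extrapolation of Treatment Effects in
    Myasthenia Gravis Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-part Bayesian model-informed analysis for extrapolating a
    placebo-controlled treatment effect on longitudinal myasthenia gravis
    scores (MG-ADL, QMG) beyond the double-blind period. Part 1 builds an
    informative prior for the control-arm trajectory by meta-regression of
    aggregate external change-from-baseline summaries on log time; Part 2
    fits a combined Bayesian individual-patient-data model using that
    prior, down-weighted by a power-prior borrowing weight, and reports
    predicted trajectories, credible intervals, threshold posterior
    probabilities and tipping-point sensitivity sweeps. Includes external
    control preparation (censoring rules, propensity-based odds weighting,
    weighted mixed model for repeated measures) and a synthetic-data
    generator emulating the statistical structure of the trial and
    registry sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
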