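Package: sofaer
Title: Exposure-Response Modelling of Longitudinal SOFA Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pharmacometric pipeline for linking steady-state drug exposure
    (AUC over one dosing interval) to longitudinal Sequential Organ Failure
    Assessment (SOFA) scores in sepsis trials. Implements a latent-variable
    inhibitory indirect-response model combined with an exponential
    standard-of-care term, nonlinear mixed-effects estimation (FOCE with an
    adaptive Gauss-Hermite reference), non-compartmental AUC derivation,
    goodness-of-fit and prediction-corrected visual predictive check
    diagnostics, dose-selection simulations, and a synthetic Phase-IIa trial
    generator so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    ggplot2,
    grDevices,
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
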