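Package: cefadial
Title: Population Pharmacokinetics of Cefazolin in Children on
    Maintenance Hemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling cefazolin exposure in children with
    kidney failure on intermittent maintenance hemodialysis.  Provides an
    exact piecewise-analytic solver for one- and two-compartment linear
    kinetics with zero-order infusions and session-gated dialysis
    clearance, the pediatric covariate model (allometric body-weight
    scaling, dialysis-membrane surface-area effect, fat-free mass and
    body-surface-area algebra), a stochastic approximation EM (SAEM)
    estimator for the nonlinear mixed-effects model, MAP-Bayes
    individualization for therapeutic drug monitoring, simulation-based
    diagnostics (NPDE, prediction-corrected VPC), and Monte Carlo
    probability-of-target-attainment with dosing-regimen optimization
    against trough/steady-state concentration bands derived from MICs.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
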