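Package: btlssvm
Title: Breakthrough-Curve Prediction with PSO-Tuned Least-Squares Support
    Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven modelling of fixed-bed adsorption breakthrough
    curves (outlet-to-inlet concentration ratio C/C0 versus run time), as
    arise in the downstream purification of rhamnolipid biosurfactants on
    polymeric resins. Fits a radial-basis-function least-squares support
    vector machine (LSSVM) by solving the Karush-Kuhn-Tucker linear system
    directly, tunes the regularization and kernel-width hyperparameters by
    particle swarm optimization, and evaluates fits with the field's
    standard statistic suite (R2, MAE, RMSE, MSE, %AAD, residual SD) plus
    leverage-based applicability-domain diagnostics (Hat matrix, warning
    leverage, Williams plot). Includes a frozen quadratic-polynomial GMDH
    reference network for model comparison and a synthetic breakthrough
    curve generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
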