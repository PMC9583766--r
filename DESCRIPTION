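Package: kkscascade
Title: Progress-Curve Analysis of a Reconstituted Kallikrein-Kinin Cascade
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic modelling of the minimal in vitro kallikrein-kinin
    system (FXIIa, prekallikrein, high-molecular-weight kininogen) as a
    two-step Michaelis-Menten proteolytic cascade. Provides the coupled
    ODE model family (presteady-state initial burst, cleaved-kininogen
    product inhibition, stopping-delay time offset, zero-order enzyme
    decay), an lsoda-based simulator of cleavage progress curves,
    sum-of-squared-distance multi-assay fitting with a
    two-significant-digit stopping rule, bootstrap Monte Carlo parameter
    dispersion, single-enzyme kinetic-parameter estimation (Hanes-Woolf
    linearisation refined by nonlinear regression) with gel and
    chromogenic-plate assay processing and quality control, and a
    synthetic-data generator reproducing the canonical assay designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
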