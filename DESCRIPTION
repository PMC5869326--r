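Package: tackit
Title: Kinetic Model Analysis of Dynamic FDG-PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("tackit", "maintainers", email = "tackit@example.org",
    role = c("aut", "cre"))
Description: Tools for tracer kinetic analysis of dynamic [18F]FDG PET
    time-activity curves (TACs). Implements Patlak graphical analysis, a
    closed-form three-parameter reversible-trapping tissue model built on a
    tri-exponential input function, and the two-tissue five-parameter
    compartment model with its Ki and kb macroparameters. Includes
    Bland-Altman agreement statistics, a packaged per-patient parameter
    table from a 21-patient lung cancer cohort, a synthetic TAC generator
    for validation, and a command-line pipeline that reproduces the cohort
    comparison end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
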