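Package: ridkin
Title: Model-Based Retinol Isotope Dilution and Whole-Body Vitamin A Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-body vitamin A tracer kinetics in a delayed
    compartmental model of retinol metabolism, derives the time-varying
    retinol isotope dilution (RID) coefficients Fa, S and FaS from the model
    solution, and predicts vitamin A total body stores from a single plasma
    retinol specific-activity measurement.  Includes a "super-person"
    population workflow: composite nonlinear least-squares fitting of pooled
    sparse plasma samples, population-level RID coefficients, per-subject
    total-body-stores prediction, and validation against synthetic
    populations of theoretical subjects with known stores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
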