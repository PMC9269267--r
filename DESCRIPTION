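Package: mbegrowth
Title: Sigmoid Growth Curves from the Briere and Modified Briere Rate Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sigmoid growth curves obtained by integrating the Briere
    rate equation and a modified form with an extra elasticity exponent to
    time-size trajectories (crop biomass, bamboo shoot height and similar
    ontogenetic growth series). Provides the rate functions and their
    analytic diagnostics (time of maximum growth rate, skew direction),
    numerical integration of the rate models, Nelder-Mead least-squares
    fitting with deterministic multi-start, model comparison by root-mean-
    square error and the five-percent absolute-percentage-error rule,
    fitting of ovate leaf outlines as two axially arranged half-width
    curves, a synthetic-data generator with known ground truth, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
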