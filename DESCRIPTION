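Package: sepx
Title: Separatrix-Crossing Analysis of Spike-Threshold Variability in
    Excitable Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for studying how the spike-generation threshold of
    excitable neuron models varies with stimulation history, using the
    separatrix (the basin boundary of the resting state) in state space.
    Provides a zoo of excitable models (quadratic integrate-and-fire,
    FitzHugh-Nagumo variants, two- and three-dimensional piecewise-linear
    models, and the classic Hodgkin-Huxley equations) with analytic
    nullclines, equilibria and Jacobians; a deterministic fixed-step
    Runge-Kutta integrator with voltage-clamp, step, ramp and impulse
    protocols; analytic separatrices (threshold point, line, plane) and
    numerically sampled quasi-separatrices; instantaneous-threshold search
    by bisection; threshold-evolution equations with a first-order
    exponential reduction; and maximum-voltage maps over clamp and pulse
    parameter planes with threshold-boundary extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    Matrix,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
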