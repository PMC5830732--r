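Package: hillgpm
Title: Hill-Kinetics Gene Regulatory Network Models via Generalized Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of Hill-function ordinary differential equation
    models of gene regulatory networks from sparse time-series data using
    the generalized profiling method: an inner penalized B-spline smoothing
    fit of the state trajectories profiled inside an outer nonlinear
    least-squares fit of the kinetic parameters. Positivity constraints are
    removed by an exponential (log-scale) reparameterization, and the
    underdetermined estimation problem is split into alternating blocks
    (cooperativity exponents versus all other parameters). Includes forward
    simulation, steady-state solvers, a synthetic benchmark generator, a
    command-line interface, and the nine-gene Escherichia coli SOS-response
    case study with published parameter estimates as an executable fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
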