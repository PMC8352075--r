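Package: acmekit
Title: Hybrid Discrete-Continuum Solver for Augmented Chemical Master Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Declarative modelling and deterministic numerical solution of
    hybrid stochastic chemical kinetics: continuum species governed by
    Fokker-Planck drift-diffusion terms, non-local jump processes with
    probability or fragmentation kernels (bursty protein production, cell
    division), and coupled discrete states whose transition rates may be
    negative ("phantom" states encoding population-level selection).  The
    semi-discrete system is discretised with a conservative second-order
    central finite-volume scheme with slope limiting and integrated with
    strong-stability-preserving Runge-Kutta time stepping under CFL control.
    Includes a truncated discrete chemical-master-equation reference solver,
    closed-form benchmark densities and mean switching-time quadratures,
    prebuilt case-study models (self-regulated gene expression, first-passage
    absorption, phenotypic selection, growth-fragmentation), and a YAML/JSON
    configuration interface with a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
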