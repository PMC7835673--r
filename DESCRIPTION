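Package: biofilmadapt
Title: Population Dynamics, Active-Matter Growth and Shear Rheology of
    Biofilms Under Hydrodynamic Stress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models how bacterial biofilms adapt to hydrodynamic stress.
    Provides a two-compartment (biofilm/planktonic) nutrient-coupled
    logistic population model integrated by fixed-step Runge-Kutta, with
    bounded multi-start least-squares fitting of the exchange parameters
    to cell-count time series; a two-dimensional run-and-tumble
    agent-based simulator of growing, dividing, weakly attracting
    rod-shaped bacteria for early colony growth; a coarse-grained
    dissipative-particle-dynamics model of a crosslinked
    bacteria-polymer-solvent network under oscillatory shear; operators
    that extract storage and loss moduli, shear viscosity and yield
    strain from oscillatory stress records; and a synthetic-data
    generator emulating the observables (log-CFU growth curves, surface
    coverage, stress-strain curves) so that inference and analysis are
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
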