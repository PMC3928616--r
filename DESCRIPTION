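Package: neurostimfem
Title: Finite-Element and Cable-Equation Modeling of Extracellular Neural Microstimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-contained simulator of extracellular electrical neural
    microstimulation. Solves the quasi-static Poisson equation for the
    stimulating potential field in microelectrode-array (MEA) chambers with
    Robin (finite surface conductance) electrode boundary conditions, computes
    compartmental cable-equation responses of neurons embedded in that field
    (the hybrid pathway), and alternatively solves the extracellular and
    intracellular potentials simultaneously with the neuron membrane treated
    as a thin-film interface carrying capacitive, leak and Hodgkin-Huxley
    ionic current densities (the whole-FEM pathway). Includes a structured
    tetrahedral mesh generator with exact cylindrical, spherical and capsule
    surfaces, Gmsh MSH import/export, stimulus-current calibration, focality
    metrics, and end-to-end scenario drivers covering ground-surface MEA
    stimulation, the mirror response of a passive fiber, and sub-compartment
    soma polarization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
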