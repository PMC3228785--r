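Package: runtumble
Title: Non-Markovian Run-and-Tumble Chemotaxis in One Dimension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates a one-dimensional run-and-tumble bacterium whose
    tumble probability is modulated by a linear memory functional of the
    chemoattractant concentration experienced along its own past
    trajectory, with no memory reset at tumbles. Response kernels are
    represented as weighted sums of delta impulses (singular, two-delta
    adaptive, or a discretised bilobe kernel resembling the measured
    wild-type E. coli response). Provides estimators for the steady-state
    density slope, the chemotactic drift velocity and the
    position-resolved diffusivity, a coarse-grained biased-diffusion
    theory (de Gennes drift, linear diffusivity field, zero-flux
    steady-state slope, superposition over impulse kernels, and the
    mapping onto direction-resolved two-species descriptions), and
    experiment orchestration that joins simulation with theory.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
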