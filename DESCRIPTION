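Package: cleftsim
Title: Particle-Based Monte Carlo Simulation of Glutamatergic Synaptic
    Transmission with Trans-Synaptic Nanocolumns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of a glutamatergic synapse in which a
    trans-synaptic nanocolumn aligns a presynaptic release site with a dense
    cluster of postsynaptic AMPA receptors. Individual glutamate molecules
    undergo Brownian motion in a cylindrical cleft with reflective and
    absorbing boundaries and hindered (anisotropic) lateral diffusion inside
    the nanocolumn; receptors follow a nine-state Markov scheme with two
    binding sites; the extracellular potential in the cleft is obtained by a
    finite-volume solve coupled to the open-channel configuration and feeds
    back on both the driving force and the drift of charged glutamate.
    Includes ensemble and release-train drivers, biexponential fitting of the
    synaptic current, summary metrics (peak current and conductance, charge
    transfer, proportion of transmitter captured), mean-square-displacement
    validation, and a catalogue of ready-made simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
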