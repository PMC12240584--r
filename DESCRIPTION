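Package: evapopore
Title: Simulation of an Isothermal Gas-Flux Evaporation Pore for Nucleic Acid
    Accumulation and Salt-Cycled Strand Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reaction-transport model of a millimetre-scale water-filled pore
    whose open gas-water interface is dried by a perpendicular gas flow at
    constant temperature. The package solves the laminar gas flow and vapor
    transport in the gas gap, derives the evaporation-velocity and shear
    profiles at the interface, solves the driven 2D Stokes flow in the liquid
    (interfacial vortex), simulates advection-diffusion of non-volatile
    solutes (DNA, Mg2+) with evaporation-driven boundary-layer accumulation,
    traces single molecules by Brownian dynamics through the resulting
    concentration fields, and evaluates sequence-level DNA duplex
    thermodynamics under varying salt (nearest-neighbor model with
    magnesium/monovalent correction) to count salt-driven strand-separation
    cycles. Synthetic bead videos and fluorescence stacks with a matching
    particle-tracking velocimetry pipeline close the loop against
    bead-tracking observations. Includes an RNA backbone hydrolysis lifetime
    estimate for the same conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
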