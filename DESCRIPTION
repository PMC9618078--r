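Package: poreflux
Title: Ion Permeation, Conductance, and Membrane Energetics from Channel
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis layer for molecular simulations of pentameric
    ligand-gated ion channels. Detects and tallies ion permeation events
    through a cylindrical channel pathway (robust to periodic wrapping and
    computational-electrophysiology position swaps), converts event counts
    into windowed currents, current-voltage conductance fits with
    confidence intervals, and selectivity ratios, reconstructs
    transmembrane potential profiles from charge densities, computes
    potentials of mean force by the weighted histogram analysis method and
    by Boltzmann inversion, profiles minimal pore radii of static
    structures, maps leaflet surfaces and membrane thickness with a
    quadratic compression free-energy penalty, and quantifies
    ligand/lipid occupancy, residence times, density maps, and ion
    coordination numbers. Includes Brownian-dynamics and two-state Markov
    generators that produce inputs with known ground truth so every stage
    is testable without running a molecular dynamics engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
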