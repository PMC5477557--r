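Package: seepsim
Title: Transport-Reaction Modelling of Methane Seepage and Gas-Hydrate
    Stability in Marine Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating the onset of methane pulses from non-steady-state
    porewater sulfate profiles with a 1-D diffusion model coupled to dual-Monod
    anaerobic oxidation of methane (AOM), for simulating the propagation of
    bottom-water temperature into shallow sediments and assessing structure-I
    methane-hydrate stability under seasonal and warming forcings, and for
    screening mechanistic explanations of "kink-type" porewater profiles with a
    simplified multi-species early-diagenesis reaction network.  Includes a
    Crank-Nicolson finite-volume transport kernel, physical-chemical constants
    and correlations (solute diffusivities, the seawater methane-hydrate phase
    boundary, methane solubility at hydrate equilibrium), synthetic-data
    generators with known truth for estimator validation, and CSV/YAML/JSON
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
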