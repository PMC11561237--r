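Package: mdsolv
Title: Trajectory Structure, Diffusion and Solubility Analysis for
    Subcritical-Water Extraction Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis chain for molecular-dynamics studies
    of solute extraction in subcritical water: radial distribution
    functions with first-peak extraction and temperature-trend analysis,
    time-origin-averaged mean square displacement with Einstein-relation
    diffusion fits, and mole-fraction solubility from solvation free
    energy with Clausius-Clapeyron sublimation-pressure extrapolation,
    Poynting correction and AARD validation.  Includes seed-deterministic
    synthetic generators (Brownian walkers, uniform and paired gases, a
    Metropolis Lennard-Jones fluid, thermodynamic truth tables) so every
    stage is testable with known ground truth, plus readers and writers
    for multi-frame XYZ and a LAMMPS text-dump dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
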