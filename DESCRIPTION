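Package: halosolv
Title: Electrolyte Activity Derivatives and Protein Hydration-Shell Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the solvation of proteins in concentrated
    electrolyte (KCl, potassium acetate) solutions from particle
    configurations and trajectories. Implements finite-size-corrected
    Kirkwood-Buff integrals and the cosolvent activity derivative of a 1:1
    electrolyte, the Pitzer ion-interaction reference model on the molal and
    molar scales, Lennard-Jones pair-parameter optimisation for
    cation-carboxylate contacts (combination rules, Rmin scaling, Gaussian
    first-peak fitting against crystallographic contact distances, an
    activity-derivative acceptance band), proximal hydration-shell number
    densities normalised by distance-resolved solvent-accessible surface
    area, a geometric strong-hydrogen-bond census, and shell-resolved
    diffusion coefficients from mean-square-displacement fits. Includes
    seeded synthetic generators (ideal and ion-paired electrolyte boxes,
    Brownian trajectories, scripted toy protein systems) so every analysis
    can be exercised and validated without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    bio3d,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
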