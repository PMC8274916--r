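Package: poroSpheroid
Title: Bio-Chemo-Poromechanical Simulation of Tumor Spheroid Growth in
    Elastic Capsules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A digital twin of multicellular tumor spheroids (MCTS) growing
    freely or confined inside elastic alginate microcapsules. The spheroid is
    modeled as a reactive porous multiphase continuum (extracellular-matrix
    scaffold, tumor-cell phase, interstitial fluid) with Biot effective
    stress, a pressure-saturation closure, oxygen reaction-diffusion, hypoxic
    necrosis and pressure-inhibited growth. Provides a monolithic implicit
    mixed finite-element solver in one-dimensional spherical (and Cartesian)
    symmetry, a Terzaghi consolidation benchmark, the thick-walled-shell
    inverse analysis turning capsule dilation into confinement pressure,
    local response-surface Sobol sensitivity indices, bounded Nelder-Mead
    parameter calibration, and a synthetic-experiment generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
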