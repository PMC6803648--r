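Package: tamsim
Title: Hybrid Continuum-Discrete Simulation of Liver Tumor Growth with
    Macrophage Polarization and ECM Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates vascularized primary and metastatic liver-seeded tumor
    growth on a 2D lattice, coupling continuum fields (oxygen, pressure,
    cytokines, extracellular matrix and matrix-degrading enzymes, solved with
    quasi-steady sparse reaction-diffusion solvers) to discrete
    tumor-associated macrophage agents that extravasate from a capillary grid,
    migrate by chemotaxis, and polarize to M1 or M2 phenotypes in response to
    local TNF-alpha and TGF-beta1 levels. Includes TAF-driven angiogenic
    sprouting, haptotaxis-modulated Darcy tissue velocity, a synthetic
    co-culture ELISA/transwell assay generator with the calibration mapping
    from assay fold-changes to model rates, and an experiment runner for the
    full control-vs-transitional ECM, primary-vs-metastatic simulation design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
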