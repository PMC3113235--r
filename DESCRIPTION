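Package: vegfgrad
Title: Steady-State VEGF Isoform Transport and Gradients Around a Capillary Sprout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-detailed steady-state reaction-diffusion simulator of
    vascular endothelial growth factor (VEGF) isoform transport in the tissue
    cylinder surrounding an endothelial sprout. Models interstitial diffusion
    in a porous extracellular matrix, reversible sequestration by heparan
    sulfate proteoglycan (HSPG) binding sites, first-order proteolytic
    cleavage to a diffusible non-heparin-binding fragment, isoform-specific
    degradation, and the VEGFR1/VEGFR2/neuropilin-1 surface receptor network
    on the sprout, including NRP1 coupling and receptor turnover. Provides an
    axisymmetric cylindrical finite-volume discretization, a pseudo-transient
    fully implicit march with red-black successive over-relaxation, two-stage
    calibration of secretion and clearance boundary fluxes, tip-cell gradient
    and occupancy metrics, affinity/protease parameter sweeps, and independent
    closed-form and one-dimensional oracles for verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
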