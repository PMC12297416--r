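Package: sptHMM
Title: Diffusional Hidden Markov Models for Single-Molecule Tracking in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-particle-tracking experiments on fluorescently
    labeled molecules in bacterial cells. Simulates multi-state Brownian
    trajectories confined to spherocylindrical cells with stroboscopic motion
    blur, localization error, photobleaching, and detection gaps; fits all
    trajectories jointly by maximum likelihood to a K-state diffusional hidden
    Markov model whose displacement emissions are corrected for motion blur,
    localization uncertainty, and missing positions; compares model sizes by
    AIC; coarse-grains fitted states into bound/free/artifact classes by
    diffusion-coefficient thresholds; and derives steady-state occupancies,
    flux-based dwell times, factor cycle times, concentration-scaled cycle
    thresholds, replicate statistics, and normalized-cell-coordinate
    occupancy maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
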