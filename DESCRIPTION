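Package: pgap
Title: Pareto-Navigation Calibrated Automated Radiotherapy Planning on
    Synthetic Prostate Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for protocol-based automatic iterative
    optimisation (PBAIO) of radiotherapy treatment plans with a
    multi-dimensional Pareto-navigation calibration layer.  Provides
    procedural generation of CHHIP-like prostate patient phantoms (targets,
    organs at risk and planning target volumes on a regular voxel grid), a
    simplified beamlet influence-matrix dose engine for a coplanar arc,
    priority-structured planning protocols with dose-volume penalty
    functions, the iterative planning loop with dynamic objective
    positioning and dynamic weighting, Pareto dataset generation with
    multilinear interpolation navigation and calibration commit, a full
    dose-volume-histogram metric panel (Dx%, Vd Gy, homogeneity and Paddick
    conformity indices), and paired-cohort comparison machinery with an
    exact Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
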