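Package: spheromigrate
Title: Quantification of Collective and Single-Cell Outgrowth from 3D Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of outgrowth from fluorescently stained
    multicellular spheroids embedded in 3D matrices. Foreground (f-actin
    positive) voxels are classified into collective migration (the connected
    network originating from the spheroid center) versus single-cell migration
    (isolated objects detached from that network), and radial migration
    distances are summarised as histograms and per-image scalar metrics.
    Includes a seeded synthetic spheroid-image generator with per-voxel ground
    truth for validation, threshold-based positive-pixel histomorphometry with
    normalization to a control group, TIFF z-stack input/output, and tidy
    tabular results with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
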