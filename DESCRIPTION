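Package: nanotopo
Title: Nanocluster Topography Analysis for Single-Molecule Localization and STED Nanoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of membrane-receptor surface topography from
    single-molecule localization microscopy (STORM) and STED nanoscopy data.
    Provides a synthetic-data generator with known ground truth, ThunderSTORM
    dialect localization table input/output, spot detection and sub-pixel
    Gaussian fitting, graph-based nanocluster detection on weighted k-nearest
    neighbour graphs with CSR-calibrated noise removal and multi-level community
    detection, alpha-shape based inter-cluster similarity merging, per-cluster
    shape/density/distance metrics, nearest-particle G-function analysis with
    complete-spatial-randomness envelopes, and photon-threshold filtering that
    reveals mesoscale organization within localization data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    igraph,
    ggplot2,
    generics,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    withr,
    jsonlite
Config/testthat/edition: 3
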