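Package: spomics
Title: Spatial Statistics and Image Features for Spatial Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infrastructure and statistics for spatially resolved omics
    data (Visium-style grids and imaging-based assays alike): spatial
    neighbour graphs (hexagonal/square grid rings, k-nearest neighbours,
    fixed radius, Delaunay triangulation) with spectral and cosine
    transforms; permutation neighbourhood enrichment, cluster interaction
    matrices and group centralities on labelled graphs; Ripley F/G/L
    point-pattern curves and cluster co-occurrence ratios; per-gene
    spatial autocorrelation (Moran's I, Geary's C) with permutation and
    analytic p-values, and a diffusion-based spatial variability score;
    a permutation ligand-receptor test across cluster pairs with
    multi-subunit complex support; and a tissue-image toolkit (tiled
    processing, watershed segmentation, per-spot summary, histogram,
    texture and segmentation features). Includes seeded generators for
    synthetic point patterns, expression matrices and blob images, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RANN,
    deldir,
    igraph,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
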