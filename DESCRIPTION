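Package: leafsurf
Title: 3D Leaf Surface Reconstruction from Focus Stacks and Trichome
    Patterning Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs smooth 3D surface models of young, curved leaves
    from conventional light-microscope focus stacks (shape-from-focus with a
    Sobel sharpness measure), fits an elastic-map principal manifold to the
    height map, and computes spatial statistics of developmentally annotated
    trichomes on the resulting triangulated surface: geodesic distances by
    fast marching, 2D/3D Euclidean distances, per-triangle distortion,
    Voronoi cell areas, meta-leaf pooling across leaves, and two-genotype
    Wilcoxon comparisons. Includes a synthetic-scene generator (textured
    surfaces with depth-dependent defocus blur and hard-core trichome point
    patterns) so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    mgcv,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
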