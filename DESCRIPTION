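Package: primordium3d
Title: 3D Cellular Morphometrics of Ovule Primordium Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D morphometric analysis of segmented, labeled
    image volumes of plant ovule primordia. Annotates cell layers (L1-L4)
    and radial contact classes around the central subepidermal (L2) cell,
    computes per-cell size and shape descriptors (volume, surface area,
    fitting-ellipsoid axes, sphericity, prolate/oblate ellipticity),
    infers recent cell divisions from geometric wall continuity and
    predicts division planes by the shortest-wall rule, stages organs by
    optimal one-dimensional clustering of central-cell volumes, and
    measures whole-organ shape (oriented bounding box, dome curvature).
    Includes a synthetic ovule generator producing labeled dome tissues
    with known ground truth for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    Matrix,
    tiff,
    yaml,
    readr,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
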