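Package: spheresketch
Title: Spherical Sketching of Single-Cell Embeddings by Radius Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects a small representative subset (a "sketch") of cells from a
    single-cell embedding so that closed balls of minimal radius centered at the
    selected cells cover every cell. The covering radius is minimized by a
    thresholding search over candidate radii, with feasibility at each radius
    tested by a greedy set cover -- either an exact greedy or a bucketed
    disk-friendly greedy -- optionally under fairness quotas that require a
    minimum number of representatives per cell class (e.g. collection time
    point). Includes a fast grid presampling stage for large inputs, sketch
    quality evaluation via the robust Hausdorff distance and class composition
    reports, a seeded Gaussian-mixture generator emulating embeddings with rare
    populations, readers for dense and Matrix Market inputs, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
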