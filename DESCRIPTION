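Package: antscape
Title: Ecological Security Patterns by Ant-Colony Corridor Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs ecological security patterns on raster landscapes:
    per-cell ecosystem-service scoring, Getis-Ord Gi* hotspot extraction of
    ecological sources, entropy-weighted basic resistance surfaces corrected
    by an ecological sensitivity index, minimum-cumulative-resistance
    least-cost corridors, and a modified ant-colony algorithm with kernel
    density estimation that turns corridor centrelines into corridors with
    explicit width, main and potential extents, and ecological restoration
    points. Includes a seeded synthetic-landscape generator emulating a
    heterogeneous karst mountain setting so the whole pipeline runs without
    external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
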