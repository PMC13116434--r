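Package: rifasurv
Title: Spatial Surveillance Analysis of Red Imported Fire Ant Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Site-level density and occurrence metrics, inverse distance
    weighted interpolation surfaces, density-weighted quartic kernel density
    surfaces, global and local Moran's I with LISA cluster classification,
    mound-volume geometry, and season-by-habitat nonparametric comparisons
    (Kruskal-Wallis, Dunn's post hoc, Benjamini-Hochberg adjustment, compact
    letter displays) for georeferenced red imported fire ant (Solenopsis
    invicta) survey data. Includes a synthetic survey generator that emulates
    the seasonal, habitat-structured, spatially clustered statistical
    structure of a city-scale four-season nest survey, so every stage of the
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
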