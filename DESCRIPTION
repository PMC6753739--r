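Package: vorolung
Title: Voronoi-Branch Lung Phantoms and Proton Bragg-Peak Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs 3D-printable lung phantoms built from the edge skeleton
    of a centroidal Voronoi tessellation (Poisson-disk seeding, Lloyd
    relaxation, radius-tuned branch network), voxelizes them onto a regular
    grid at a prescribed bulk density, and estimates the resulting proton
    Bragg-peak degradation with a per-ray water-equivalent path length
    (WEPL) range-mixing transport model. Includes an analytic pristine
    Bragg-curve model calibrated to a measured distal falloff width,
    spread-out Bragg peak construction, falloff and peak-value analysis, and
    the closed-form binomial heterogeneity model for the range-mixing sigma.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
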