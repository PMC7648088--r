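Package: fibroswarm
Title: Quantification of Collective Fibroblast Migration in Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify collective ("swarming") fibroblast migration in
    wound-healing imaging experiments. Implements iterative cross-correlation
    particle image velocimetry with normalized-median-test vector validation,
    a Delaunay-neighbour movement-similarity score for 3D cell tracks, track
    kinematics (3D step displacement, velocity, landmark displacement),
    box-counting fractal dimension and lacunarity, structure-tensor orientation
    fields, leading-front contour trajectory prediction, fluorescence enrichment
    indices, and trichrome histology quantification (nuclei counts, collagen
    scar area). An agent-based swarm simulator and synthetic movie renderer
    provide ground-truth inputs for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
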