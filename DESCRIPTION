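Package: vogtbailey
Title: Feature Similarity Gradients and the Vogt-Bailey Index on Surfaces
    and Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds non-negative affinity graphs from per-vertex feature
    vectors (for example resting-state fMRI time series), extracts Laplacian
    eigenmap gradients (Fiedler vector, spectral reordering, RGB eigenmaps)
    and computes the Vogt-Bailey index -- the normalised algebraic
    connectivity of a graph Laplacian -- in whole-region, per-cluster and
    vertex-wise searchlight modes, on triangulated surface meshes and on 2D
    raster images where pixels act as vertices.  Includes minimal GIFTI
    surface I/O, icosphere mesh generation and deterministic synthetic
    parcellated time-series generators for validation, plus a command line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    grDevices,
    utils,
    parallel,
    xml2,
    jsonlite,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
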