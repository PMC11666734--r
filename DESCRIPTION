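Package: ssmrec
Title: Statistical Shape Model Reconstruction of Fractured Hemipelves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual reconstruction of fractured hemipelves from surface
    meshes. Builds a PCA statistical shape model (SSM) from a population of
    intact shapes placed in dense point-to-point correspondence by non-rigid
    iterative closest point registration, reconstructs an intact shape from
    the merged fragment surfaces of a fracture by masked subspace fitting,
    and evaluates reconstruction quality with whole-surface and regional
    RMSE, per-vertex distance maps, and six plate-fitting clinical
    parameters (iliopectineal and ischial line length and curvature radius,
    acetabular diameter, quadrilateral slope). Includes mesh I/O (STL, PLY,
    OBJ), isotropic remeshing, hole filling, a synthetic-anatomy generator
    with ground-truth landmarks for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
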