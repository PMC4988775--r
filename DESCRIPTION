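Package: ToothField
Title: Concavity-Aware Segmentation Fields for Tooth Separation on Dental Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive separation of individual teeth from 3D dental surface
    meshes. A constrained harmonic scalar field (the segmentation field) is
    solved per user click on a concavity-aware discrete Laplacian, iso-contours
    are sampled from the field, and the maximum-gradient contours inside
    concave seams become the cutting boundaries. Includes triangle-mesh I/O
    (OFF/OBJ/PLY/STL), discrete differential-geometry primitives, a simplified
    feature-point detector for automatic constraint placement, exact mesh
    cutting along iso-contours, and deterministic synthetic dental-arch
    generators with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
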