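Package: gastro3d
Title: Post-Processing Toolkit for Whole-Organ 3D Reconstruction from
    Monocular Endoscope Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational stages that turn the sparse structure-from-motion
    output of a monocular endoscope video into a clean, colored 3D organ
    model: duplicated-frame removal by pixel-difference ratio, a four-stage
    point-cloud outlier-removal cascade built on local RANSAC plane fitting,
    surface-normal estimation and camera-based orientation, implicit surface
    meshing with per-vertex color transfer, and descriptor-based frame
    retrieval and localization onto the mesh.  Reads and writes the standard
    sparse-model text format (cameras/images/points3D) and PLY point clouds
    and meshes, and ships a fully labeled synthetic-scene generator (bumpy
    closed cavity, planted outliers, interior camera trajectory, duplicate
    frames) so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
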