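Package: scaffoldCT
Title: Quantitative 3D Micro-CT Analysis of Electrospun Fibrous Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the three-dimensional structure of
    electrospun polymer scaffolds with embedded ceramic microparticles from
    reconstructed micro-computed-tomography volumes. Provides maximum-entropy
    (Kapur) phase segmentation into background, fiber and particle classes,
    topology-preserving 3D skeletonization, structure-tensor fiber
    orientation and ray-cast fiber diameter estimation at skeleton points,
    18/26-connectivity particle-aggregate labeling with equivalent-sphere
    sizing, voxel-count porosity, and one-way ANOVA with Tukey HSD group
    comparison. A synthetic phantom generator produces fiber/particle
    volumes with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
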