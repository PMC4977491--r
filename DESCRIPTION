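Package: skullmorph
Title: Landmark-Based Geometric Morphometrics of Crania and Mandibles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for 3D landmark-based shape analysis of skeletal
    material: reading and writing TPS and tabular landmark files, estimation
    of missing landmarks by mirror-imaging across the midsagittal plane and
    by thin-plate-spline interpolation from a reference, generalized
    Procrustes analysis with unit-centroid-size scaling and tangent-space
    projection, extraction of the symmetric component of shape for
    bilaterally symmetric structures, total and between-group principal
    component analysis, allometric regression, size ANOVA with Tukey HSD,
    MANOVA on retained principal component scores, among-group Mahalanobis
    distances, and Neighbor-Joining trees with specimen-level bootstrap
    support. A synthetic landmark-data generator with known ground truth
    supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
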