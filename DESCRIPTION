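Package: toothmatch
Title: Contralateral Pair Matching of Anterior Teeth from 3D Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies bilateral shape correspondence of maxillary anterior
    teeth from triangle meshes. A tooth and its mirrored contralateral are
    superimposed by three-landmark rigid alignment followed by a constrained
    point-to-plane iterative closest point step (rotation about the tooth long
    axis, translation in the perpendicular plane); crown and emergence-profile
    elements are separated along the gingival margin curve and its 3 mm
    geodesic offset; similarity is scored by the symmetric Hausdorff distance
    between sampled element surfaces; and a match threshold is calibrated by
    ROC analysis at full specificity. Includes STL input/output, surface-curve
    tools (periodic splines, geodesic offset level sets), and a seeded
    generator of synthetic bilateral tooth populations with controlled
    inter-individual variation and left/right asymmetry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
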