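Package: mplexmorph
Title: Multiplex Patch-Correlation Networks for Structural Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Patch-based multiplex-network morphometry for co-registered
    structural MRI. Volumes are tiled into fixed-size rectangular patches
    per hemisphere; each subject contributes one layer of a multiplex
    network whose edges are thresholded pairwise Pearson correlations
    between patch intensity vectors. Single-layer (strength, inverse
    participation ratio, degree-conditional means) and multiplex
    (aggregate-degree weighted) node features feed a repeated
    cross-validated random-forest wrapper with a binomial occurrence test
    for feature selection, followed by classification with bootstrap
    uncertainty, permutation and voxel-shuffle robustness experiments, and
    atlas back-mapping of significant nodes. A seeded synthetic atrophy
    phantom makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
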