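Package: ecprofiler
Title: High-Content Phenotypic Profiling of Endothelial Cell Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for high-content characterization of
    confluent endothelial-cell monolayers imaged with a nuclear stain, a
    VE-cadherin junction marker, and an activated-NOTCH spot marker.
    Provides a ground-truthed synthetic monolayer-image simulator, tile
    stitching, seeded nucleus and cell segmentation, ridge-based
    junction-object quantification (the per-nucleus junction-object count
    J_n), subcellular NOTCH-activation classification with cell-contact
    cluster context features, a 47-feature morphometric and
    intensity-distribution registry, and area-level multivariate profiling
    by principal component analysis and hierarchical clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
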