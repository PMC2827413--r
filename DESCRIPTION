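Package: tubertools
Title: X-ray CT Tuber Volumetry, Growth Kinetics and Starch Co-Expression
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-vivo potato tuber phenotyping and starch-pathway
    transcriptomics. Implements grey-level window segmentation and
    voxel-counting volumetry of reconstructed X-ray computed tomography
    volumes, growth-velocity estimation from repeated volume measurements,
    a three-step microarray normalization with volcano-plot differential
    selection (replicate-gated Benjamini-Hochberg correction),
    cross-experiment intersection, correlation-distance K-means
    co-expression clustering with transcription-factor candidate
    extraction, and Pfaffl-method relative qPCR quantification. Ships
    seeded synthetic-data generators (voxel phantoms with a parallel-beam
    projection/filtered-back-projection simulator, planted-cluster
    expression matrices, Ct tables) so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
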