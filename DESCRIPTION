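Package: vesselchip
Title: Vascular Network Morphometry and Screening Statistics for
    Organ-on-Chip Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for fluorescence images of
    microvascular networks grown in organ-on-chip drug screens.  Provides
    rolling-ball background subtraction, three-class vessel segmentation
    (background / thin / thick), skeletonization with branch-and-junction
    graph extraction, fifteen morphometric vessel descriptors, and the
    plate-level screening statistics layer (vehicle-control normalization,
    replicate reproducibility, PCA/t-SNE phenotypic profiling, ANOVA/Tukey
    and Kruskal-Wallis/Dunn group comparisons, Wilcoxon tests with
    Benjamini-Hochberg correction, Welch t-tests).  A fully ground-truthed
    synthetic-data generator produces vascular chip images and complete
    multi-plate screens so the whole pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rtsne,
    cluster,
    grDevices,
    igraph,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
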