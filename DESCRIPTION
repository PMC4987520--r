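Package: bcellkit
Title: Window-Based ChIP-Seq Peak Calling and B-Cell Progenitor Assay
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a window-based ChIP-seq peak caller (duplicate
    removal, 150-bp read extension, 50-bp window counts, input-normalized
    Poisson enrichment test, three-consecutive-window significance rule),
    interval annotation (TSS-distance classification, basal-plus-extension
    peak-to-gene association, overlap counting, signal metaprofiles), a
    fold-change plus Poisson differential-accessibility rule for ATAC-seq
    count matrices, and bench-assay statistics for B-lymphoid development
    studies: Ig V(D)J rearrangement frequencies from qPCR cycle thresholds
    (2^deltaCt), comet-assay tail-moment outlier calling by median absolute
    deviation, gammaH2AX focus scoring, and peripheral-blood lineage cell
    counts. Ships synthetic-data generators with known ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    methods,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
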