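Package: hicbgc
Title: Hi-C Interaction Screening for Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 3D-genomics screen for biosynthetic gene clusters (BGCs)
    from binned Hi-C contact maps. Implements virtual-4C viewpoint
    extraction, a per-chromosome log2 / z-score / normal-tail /
    Benjamini-Hochberg interaction statistic with a targeted
    candidate-region test, A/B compartment PC1 from observed/expected
    correlation, base-coverage enrichment of transposable-element
    annotation classes, and proximity-based BGC and tandem-array calling
    from family-labelled gene models. Ships a synthetic-data generator
    with planted, recorded ground truth (power-law distance decay, TAD
    blocks, checkerboard compartments, Poisson interchromosomal
    background, planted viewpoint-target contacts, a BGC-like gene
    arrangement and a tandem array with elevated TE density) so the whole
    pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
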