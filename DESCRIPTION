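Package: spathet
Title: Spatial Transcriptomics Analysis of Tumor Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting intratumor heterogeneity in spatial
    transcriptomics and matched single-cell data. Implements
    expression-based copy number inference relative to a stromal
    reference, per-spot CNV burden with the (score - 1)/(max - 1)
    normalization, clone detection and clonal-tree construction from
    shared CNV events, hypergeometric multimodal intersection analysis
    (MIA) of cell-type enrichment, a geometric-mean tumor score with a
    chi-square co-localization test, and NMF-based extraction of
    intratumor expression programs with Jaccard clustering into
    meta-programs. Ships a synthetic cohort generator with planted
    clones, cell-type signatures and shared programs for end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
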