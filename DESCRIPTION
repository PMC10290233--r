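Package: speckr
Title: Cell Surface Receptor Abundance Estimation from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised estimation of relative cell-surface receptor
    abundance from single-cell RNA-seq count matrices. Counts are
    log-normalized, approximated by a reduced-rank reconstruction whose rank
    is chosen by a run-length heuristic on the drops between successive
    principal-component standard deviations, and each gene is then thresholded
    by optimal univariate k-means clustering: when the reconstructed values of
    a gene form more than one cluster, all members of the lowest-mean cluster
    are set to zero, exploiting the bimodality of surface-protein expression.
    Includes CITE-seq evaluation utilities (centered log-ratio normalization
    of antibody-derived tag counts, per-receptor rank correlations and a
    proportion-best summary) and a seeded generator of paired synthetic
    scRNA-seq/ADT data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    methods,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
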