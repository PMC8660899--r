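Package: ovoproteome
Title: Stage-Paired Differential Analysis of Oocyte and Embryo Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free proteome and companion transcriptome
    analysis of staged oocytes and preimplantation embryos under two
    ovulation treatments. Implements riBAQ (relative intensity-based
    absolute quantification) normalization, detection and constitutive-
    expression filtering, replicate averaging, quantile normalization,
    an exact sign-flip permutation test on the Wilcoxon signed-rank
    statistic for stage-paired treatment contrasts with Benjamini-
    Hochberg false discovery rate control, a stage-wise fold-change
    census, sample clustering and principal-component treatment-
    separation diagnostics, hypergeometric gene-set over-representation
    with an Enrichr-style combined score, morphometric and contingency-
    table phenotype statistics, and a synthetic data generator with
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
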