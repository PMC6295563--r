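Package: tgfomics
Title: Integrative Multi-Omics Analysis of TGF-beta1-Induced Expression and
    Epigenetic Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the integrative analysis of TGF-beta1
    treated mesangial cells: negative-binomial differential expression of
    genes, miRNAs, and genomic regions with Benjamini-Hochberg false discovery
    control; quintile rank-shift analysis of endogenous expression; scoring of
    miRNA-target anticorrelation (FC1/FC2); differential DNA-methylation
    (MeDIP-seq) and H3K27me3 (ChIP-seq) region calling from replicate peak
    sets and deduplicated read counts; RPKM-normalised metagene and
    gene-element coverage profiles; and sign-concordance integration of
    expression with epigenetic marks.  Includes a synthetic multi-omics data
    generator with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
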