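Package: rsnpleio
Title: Pleiotropic Signatures of Regulatory SNPs from Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-phase pipeline for discovering pleiotropic regulatory
    SNPs (rSNPs) in inbred crop panels. Phase 1 scans allele-specific
    promoter flanking sequences against a position weight matrix library
    with MATCH-style information-weighted scoring and classifies each
    variant as gain, loss, or no strong effect on transcription factor
    binding. Phase 2 ranks rSNPs per quantitative phenotype with a
    Boruta-style shadow-feature wrapper around random forest regression
    and picks the optimal marker count by incremental feature selection
    on out-of-bag R-squared. Phase 3 builds a binary rSNP profile matrix
    over phenotypes and transcription factors, converts it to a
    Proportional Similarity Index association matrix, and clusters it
    with Markov clustering, pruning variants associated with a single
    phenotype. Phase 4 assembles three-layer transcription factor to
    rSNP(gene) to phenotype networks and validates each rSNP by an
    allele-split Wilcoxon test on median-of-ratios normalized expression.
    A synthetic-data generator with machine-readable ground truth drives
    recovery tests of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    igraph,
    jsonlite,
    mclust,
    methods,
    ranger,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
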