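Package: sumowaves
Title: Multi-Omics Time-Course Analysis of Sumoylation During Adipocyte Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dynamics of the sumoylation pathway over
    an adipocyte differentiation time course from multiple omics assays:
    quantification of nascent transcription from SLAM-seq T>C conversions in
    3' UTR reads, post-processing of endogenous SUMO-2/3 proteomics evidence
    (peptide-level filtering, site mapping, SUMO density and the free /
    conjugated / chain / immature SUMO equilibrium), differential SUMO
    ChIP-seq landscapes over a union peak set, and module-based integration
    of time-course profiles across datasets (k-means stage modules,
    per-feature Pearson correlation, hypergeometric overlap statistics).
    A synthetic-data module generates every input format with known ground
    truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
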