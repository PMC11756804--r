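Package: cernet
Title: Direction-Consistent ceRNA Network Inference from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A staged analysis pipeline for building competing endogenous RNA
    (ceRNA) networks from bulk RNA sequencing of a two-group design: coding
    potential screening of assembled transcripts, negative-binomial
    differential expression with median-of-ratios normalization and
    Benjamini-Hochberg correction across lncRNA, miRNA and mRNA layers,
    core-lncRNA prioritization by expression and significance ranks,
    subcellular localization gating, target-prediction score thresholding
    with direction-consistency (sponge) filtering, lncRNA-miRNA-mRNA triplet
    assembly with network export, protein-protein interaction hub-gene
    extraction by graph centrality, and hypergeometric over-representation
    analysis. Includes a synthetic data generator that plants differential
    expression and ceRNA triplets so every stage is testable without access
    to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    fgsea,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    DESeq2,
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
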