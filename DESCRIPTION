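Package: circseed
Title: Anchor-Based circRNA Detection, Annotation, and Functional Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for circular RNA (circRNA) analysis in
    plant transcriptomes: detection of back-splice junctions from RNA-seq
    reads by split-anchor alignment with canonical GU/AG splice-signal and
    read-support filters, positional classification of circRNAs against gene
    models (within-gene, gene-overlapping, intergenic; CDS/UTR/intron
    back-splice site labels; alternative circularization), expression
    quantification (junction RPM, circular-to-linear ratio, parent-gene RPKM),
    tissue-specificity scoring, count-based differential expression with
    Benjamini-Hochberg FDR control, prediction of circRNAs acting as miRNA
    decoys (target mimics) under plant-specific duplex pairing rules,
    construction of circRNA-miRNA-mRNA (ceRNA) networks, and cross-species
    conservation via reciprocal-best-hit orthologs. Includes a synthetic-data
    generator that plants circRNAs, decoy sites, expression profiles, and
    ortholog pairs with full ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
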