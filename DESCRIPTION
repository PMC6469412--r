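Package: lncfunnel
Title: Discovery and Annotation of Novel Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A downstream analysis pipeline for novel long non-coding RNA
    (lncRNA) discovery from an assembled two-group RNA-seq transcriptome.
    Implements a stringent stepwise filtering funnel (transcript structure,
    expression, homology, protein domains, coding-potential majority
    voting, open reading frame length, and gene proximity), positional
    classification into intergenic (lincRNA) and intronic (ilncRNA)
    classes, breed- or condition-specific expression calls, cis/host/trans
    target prediction, cross-species conservation and synteny testing,
    QTL co-localization, integrated co-expression plus protein-protein
    interaction network construction with cohesiveness-based overlapping
    module detection, and local over-representation analysis. A seeded
    synthetic-data generator emits a complete miniature study world with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    igraph,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
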