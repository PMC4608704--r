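Package: retrodup
Title: Retroduplication Variation Analysis in Population Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of retroduplication variations
    (RDVs), polymorphisms in which a retrocopy of a gene is present in some
    individual genomes and absent from others. Provides retrocopy calling
    from translated protein-to-genome alignments with intron-loss and
    ORF-conservation inference, deletion-based RDV detection with
    per-population allele frequencies from structural-variant genotypes,
    ancestrality and origin-lineage inference from whole-genome alignment
    blocks on a eutherian species tree, discovery of retrocopies absent from
    a reference genome by assembly of unmapped reads, expression flagging and
    negative-binomial differential expression between populations, and qPCR
    relative quantification. A synthetic-data generator with machine-readable
    ground truth emulates every input so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
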