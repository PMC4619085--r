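Package: crisprDel
Title: Paired Guide RNA Design and In Silico Genotyping for CRISPR
    Deletion of Genomic Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design toolkit for dual-gRNA CRISPR deletion of genomic
    elements such as promoters and non-coding loci. Enumerates and
    filters SpCas9 protospacers (NGG PAM), selects guide pairs that
    bracket a target region under the U6/H1 slotting rules, assembles
    the single 165-nt cloning oligonucleotide carrying both targeting
    sequences, simulates the two-step Type IIS (BsmBI) cloning of the
    dual-cassette construct, predicts diagnostic PCR amplicon sizes for
    wild-type, deleted and inverted alleles, and classifies clone
    genotypes from band patterns. A seeded synthetic-locus and allele
    simulator makes the whole workflow testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
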