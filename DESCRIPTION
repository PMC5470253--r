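Package: skipquant
Title: Quantification and Interpretation of CRISPR-Induced Exon Skipping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and interpreting cassette-exon skipping in
    CRISPR-edited cell lines. Quantifies percent spliced-in (PSI) from
    junction-spanning RNA-seq reads, calls differential splicing events
    between edited clones and parental cells with a conjugate beta-binomial
    Bayes factor, measures indel spectra at Cas9 target sites from amplicon
    deep-sequencing alignments, and predicts transcript-level consequences
    of exon skipping and kilobase-scale genomic deletions: reading-frame
    phase, downstream in-frame start codons, RT-PCR product sizes, and
    fusion transcripts from deletion alleles. Ships seeded simulators for
    spliced junction reads, edited amplicon reads, deletion-bearing alleles
    and overdispersed gene-level counts, each with a truth table, so every
    estimator is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
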