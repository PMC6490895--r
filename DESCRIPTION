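Package: halotx
Title: Transcript Calling, Classification and Coding-Potential Screening
    for Haloarchaeal Mixed RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments strand-specific RNA-Seq coverage of a multi-replicon
    haloarchaeal genome into transcripts (minimum-coverage rule with
    ORF-bridged gaps), classifies them into protein-coding (cdRNA),
    cis-antisense (asRNA), internal sense (isRNA) and intergenic (igRNA)
    transcripts, derives operon structures, UTR lengths, convergent
    3'-end overlaps and transcription-start-site support, and screens the
    non-coding classes for overlooked small proteins via three-frame ORF
    finding, isoelectric-point filtering and codon-usage-preference
    profiling. Ships a synthetic-data generator that emulates a
    GC-rich, acidic-proteome haloarchaeal transcriptome with planted
    ground truth, so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, Annotation, Coverage, GenePrediction
RoxygenNote: 7.3.3
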