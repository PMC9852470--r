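Package: psiNano
Title: Detection of Uridine Modifications from Nanopore Direct RNA
    Sequencing Mismatch Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-quantitative detection of pseudouridine and other
    uridine modifications from nanopore direct RNA sequencing. Compares
    U-to-C basecalling mismatch between a native (direct) library and an
    in-vitro-transcribed (IVT) unmodified control, scores each uridine
    site with a 5-mer- and coverage-aware binomial tail test, calls
    sites by replicate consensus, classifies hypermodification types I
    and II, annotates sites on transcript anatomy, and quantifies
    single-read co-modification on long reads. Includes a truth-labelled
    read simulator so the whole pipeline can be validated end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epitranscriptomics, Sequencing, RNASeq, Transcriptomics,
    Coverage, Alignment
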