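Package: tagTSS
Title: Transcription Start Site Discovery from 5'-Tag RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bacterial 5'-tag RNA-seq (tagRNA-seq) libraries, in
    which distinct sequence tags ligated to 5'-monophosphate (processed) and
    converted 5'-triphosphate (primary) transcript ends allow transcription
    start sites (TSSs) to be separated from RNA processing sites. The package
    demultiplexes and trims tagged reads, builds strand-specific 5'-end start
    tracks and read-depth tracks from SAM alignments, quantile-normalizes
    tracks across samples, subtracts processed from primary signal to call
    and classify TSSs (gene TSS, intragenic, antisense; leaderless versus
    extended-leadered 5'UTRs), quantifies expression as gene counts, RPKM and
    TPM with genome-wide ranking, infers transcription units with terminator
    and attenuator annotation, screens precursor-peptide genes for dedicated
    TSSs, and filters DNA-affinity-capture candidate regulators. A fully
    ground-truthed tagRNA-seq read simulator is included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ShortRead,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
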