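# Shared fixture builders. Everything is generated in code at test time;
# no data files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(Biostrings)
})

# small cluster-only fixture for unit tests
smallFixture <- function(seed = 1L) {
    generateGenome(length = 20000L, nGenes = 13L, layout = "btm-like",
                   seed = seed)
}

# in-memory GAlignments builder for track/count tests
mkAln <- function(pos, cigar = "75M", strand = "+", qname = NULL,
                  seqLength = 1e6L) {
    n <- length(pos)
    cigar <- rep_len(cigar, n)
    strand <- rep_len(strand, n)
    if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
    gal <- GenomicAlignments::GAlignments(
        seqnames = S4Vectors::Rle("chr", n), pos = as.integer(pos),
        cigar = cigar,
        strand = S4Vectors::Rle(GenomicRanges::strand(strand)),
        seqlengths = c(chr = as.integer(seqLength)))
    mcols(gal)$qname <- qname
    gal
}

# genes GRanges builder
mkGenes <- function(start, end, strand = "+", ids = NULL) {
    if (is.null(ids)) ids <- sprintf("g%02d", seq_along(start))
    gr <- GRanges("chr", IRanges(start, end), strand = strand)
    mcols(gr)$gene_id <- ids
    gr
}

# run the pipeline from a simulation: split the truth SAM by the demux
# class of each read (classifyReads on the simulated reads) and build the
# two start tracks
simTracks <- function(fx, sim, sample = "wt") {
    paths <- writeSimulatedReads(sim, tempfile())
    aln <- readSam(paths[["sam"]])
    cls <- classifyReads(ShortRead::sread(sim$reads))
    byId <- setNames(as.character(cls$tag_class),
                     as.character(ShortRead::id(sim$reads)))
    qn <- mcols(aln)$qname
    L <- sim$genomeLength
    list(aln = aln,
         primary = buildStartTrack(aln[byId[qn] == "primary"], L,
                                   "primary", sample),
         processed = buildStartTrack(aln[byId[qn] == "processed"], L,
                                     "processed", sample))
}

# sensitivity of calls against planted sites of one kind, within +/- tol
siteRecovery <- function(calls, sites, kind = "TSS", tol = 1L) {
    s <- sites[sites$kind == kind, ]
    found <- vapply(seq_len(nrow(s)), function(i) {
        any(abs(start(calls) - s$position[i]) <= tol &
            as.character(strand(calls)) == s$strand[i])
    }, logical(1))
    mean(found)
}
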