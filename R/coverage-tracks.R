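## SAM ingestion and track construction. Alignment itself is upstream
## (Bowtie2 territory); alignments are consumed as SAM.

#' Read a SAM file of aligned tagRNA-seq reads
#'
#' Converts the SAM to BAM with Rsamtools (so the parsing, header and CIGAR
#' validation are htslib's) and loads mapped records in file order.
#' Unmapped records are skipped and counted in
#' `metadata(x)$unmapped`.
#'
#' @param path path to a SAM file with an `@SQ` header line.
#' @param primaryOnly if `TRUE`, restrict to non-secondary alignments. By
#'   default all mapped records are counted.
#' @return A [GenomicAlignments::GAlignments] with `qname` and `flag`
#'   metadata columns; `metadata()` holds the `unmapped` skip count.
#' @export
readSam <- function(path, primaryOnly = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    dest <- tempfile()
    bam <- asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    flag <- if (primaryOnly)
        scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE)
    else scanBamFlag(isUnmappedQuery = FALSE)
    gal <- readGAlignments(bam, param = ScanBamParam(what = c("qname", "flag"),
                                                     flag = flag))
    unmapped <- countBam(bam, param = ScanBamParam(
        flag = scanBamFlag(isUnmappedQuery = TRUE)))$records
    metadata(gal)$unmapped <- unmapped
    gal
}

## 5'-side soft clip length per alignment: leading S for + strand,
## trailing S for - strand. Hard clips don't consume query bases we see,
## so only S is considered.
.softclip5 <- function(cig, strand) {
    lead <- trail <- integer(length(cig))
    i <- grepl("^[0-9]+S", cig)
    lead[i] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cig[i]))
    j <- grepl("[0-9]+S$", cig)
    trail[j] <- as.integer(sub("^.*?([0-9]+)S$", "\\1", cig[j]))
    ifelse(strand == "+", lead, trail)
}

#' 5'-end genomic positions of alignments
#'
#' The tagRNA-seq signal lives at the first transcribed base, so each
#' alignment contributes the genomic position of its 5'-most aligned base:
#' the leftmost position on the + strand, `leftmost + reference span - 1`
#' on the - strand. Alignments whose 5' side is soft-clipped by more than
#' `max5pSoftclip` bases are rejected (a clipped 5' end no longer marks the
#' transcript start); the rejection count is a metadata field, not an
#' error.
#'
#' @param aln a [GenomicAlignments::GAlignments] (e.g. from [readSam()]).
#' @param max5pSoftclip maximum tolerated 5'-side soft clip (default 3 nt).
#' @return A width-1 [GenomicRanges::GRanges] of accepted 5' positions with
#'   a `qname` column; `metadata()$rejected` counts rejected alignments.
#' @export
fivePrimePositions <- function(aln, max5pSoftclip = 3L) {
    str <- as.character(strand(aln))
    clip <- .softclip5(cigar(aln), str)
    keep <- clip <= max5pSoftclip
    pos <- ifelse(str == "+", start(aln), end(aln))
    qn <- mcols(aln)$qname
    if (is.null(qn)) qn <- rep(NA_character_, length(aln))
    gr <- GRanges(seqnames = as.character(seqnames(aln))[keep],
                  ranges = IRanges(pos[keep], width = 1L),
                  strand = str[keep],
                  qname = qn[keep])
    metadata(gr)$rejected <- sum(!keep)
    gr
}

#' Build a strand-specific 5'-end start track
#'
#' Counts accepted alignment 5' ends at each genomic position, per strand.
#' The total track mass equals the number of accepted alignments.
#'
#' @param aln a [GenomicAlignments::GAlignments], or a width-1
#'   [GenomicRanges::GRanges] of precomputed 5' positions (as from
#'   [fivePrimePositions()]).
#' @param genomeLength genome length in nt.
#' @param class transcript class of the contributing reads ("primary" or
#'   "processed").
#' @param sample sample identifier.
#' @param max5pSoftclip passed to [fivePrimePositions()] when `aln` is a
#'   GAlignments.
#' @return A [StartTrack-class].
#' @export
buildStartTrack <- function(aln, genomeLength, class = "primary",
                            sample = "sample1", max5pSoftclip = 3L) {
    sites <- if (is(aln, "GAlignments"))
        fivePrimePositions(aln, max5pSoftclip) else aln
    pos <- start(sites)
    if (length(pos) && (min(pos) < 1L || max(pos) > genomeLength)) {
        bad <- which(pos < 1L | pos > genomeLength)[1L]
        id <- mcols(sites)$qname[bad]
        stop(sprintf("5' position %d of read %s outside genome [1,%d]",
                     pos[bad], ifelse(is.na(id), "<unknown>", id),
                     genomeLength))
    }
    str <- as.character(strand(sites))
    plus <- tabulate(pos[str == "+"], nbins = genomeLength)
    minus <- tabulate(pos[str == "-"], nbins = genomeLength)
    startTrack(plus, minus, class = class, sample = sample)
}

#' Build a per-nucleotide depth track
#'
#' `depth[p]` is the number of alignments whose reference span covers `p`;
#' the span runs from the leftmost to the rightmost reference-consuming
#' CIGAR operation (M/D/N/=/X), so deletions and skips inside an alignment
#' are counted as covered. Total depth equals the sum of reference spans.
#'
#' @param aln a [GenomicAlignments::GAlignments].
#' @param genomeLength genome length in nt.
#' @param sample sample identifier.
#' @return A [DepthTrack-class].
#' @export
buildDepthTrack <- function(aln, genomeLength, sample = "sample1") {
    if (length(aln) && max(end(aln)) > genomeLength) {
        bad <- which(end(aln) > genomeLength)[1L]
        id <- mcols(aln)$qname[bad]
        stop(sprintf("alignment of read %s ends at %d, outside genome [1,%d]",
                     ifelse(is.null(id) || is.na(id), "<unknown>", id),
                     end(aln)[bad], genomeLength))
    }
    depth <- numeric(genomeLength)
    if (length(aln)) {
        cov <- as.numeric(IRanges::coverage(
            IRanges(start(aln), end(aln)), width = genomeLength))
        depth <- cov
    }
    depthTrack(depth, sample = sample)
}
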