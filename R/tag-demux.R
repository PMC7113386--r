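## Read sorting by 5' sequence tag: the first step of the tagRNA-seq
## analysis. Tags are searched only at the very 5' terminus of the read
## (the ligation chemistry places them there), never internally.

## Vectorized Hamming distance between fixed-length prefixes and one tag.
.prefixMismatches <- function(prefixes, tag) {
    k <- nchar(tag)
    mm <- integer(length(prefixes))
    for (i in seq_len(k)) {
        mm <- mm + (substr(prefixes, i, i) != substr(tag, i, i))
    }
    mm
}

.classifyCore <- function(seqs, primary, processed, maxMismatch) {
    k <- nchar(primary)
    n <- length(seqs)
    cls <- rep("untagged", n)
    long <- nchar(seqs) > k
    if (any(long)) {
        pre <- substr(seqs[long], 1L, k)
        mmP <- .prefixMismatches(pre, primary)
        mmQ <- .prefixMismatches(pre, processed)
        isP <- mmP <= maxMismatch
        isQ <- mmQ <= maxMismatch
        sub <- rep("untagged", sum(long))
        sub[isP & !isQ] <- "primary"
        sub[isQ & !isP] <- "processed"
        sub[isP & isQ] <- "ambiguous"
        cls[long] <- sub
    }
    list(class = cls, short = sum(!long), tagLength = k)
}

#' Classify reads by their 5' sequence tag and trim the tag
#'
#' Compares the first `nchar(tag)` bases of each read against the primary
#' and processed tags at the configured mismatch tolerance and removes the
#' tag prefix from tagged reads. Reads matching neither tag are left
#' untouched and classed `untagged`; reads matching both (impossible with a
#' valid [TagSpec-class], whose tags must differ by more than twice the
#' tolerance) are classed `ambiguous`. Reads no longer than the tag cannot
#' carry one and are classed `untagged`; their number is returned in the
#' `short_reads` attribute and raised as a warning.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of read
#'   sequences (tag included, 5' to 3').
#' @param tags a [TagSpec-class], or a length-2 character vector
#'   `c(primary, processed)` for relaxed (unvalidated) tag pairs.
#' @param maxMismatch mismatch tolerance; ignored when `tags` is a
#'   [TagSpec-class] (which carries its own).
#' @return A data.frame with columns `tag_class` (factor: primary,
#'   processed, untagged, ambiguous) and `trimmed` (character; tag removed
#'   for tagged classes, original sequence otherwise), plus attribute
#'   `short_reads`.
#' @examples
#' classifyReads(c("TAATGCGCACGTACGT", "CTGAAGCTGGGGTTTT", "ACGTACGTACGT"),
#'               tagSpec())
#' @export
classifyReads <- function(seqs, tags = tagSpec(), maxMismatch = 0L) {
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    if (is(tags, "TagSpec")) {
        primary <- tags@primary
        processed <- tags@processed
        maxMismatch <- tags@maxMismatch
    } else {
        stopifnot(length(tags) == 2L)
        primary <- toupper(tags[[1L]])
        processed <- toupper(tags[[2L]])
        if (nchar(primary) != nchar(processed))
            stop("tags must have equal length")
    }
    res <- .classifyCore(seqs, primary, processed, as.integer(maxMismatch))
    tagged <- res$class %in% c("primary", "processed")
    trimmed <- seqs
    trimmed[tagged] <- substr(seqs[tagged], res$tagLength + 1L,
                              nchar(seqs[tagged]))
    if (res$short > 0L)
        warning(sprintf("%d read(s) not longer than the tag; classified untagged",
                        res$short))
    out <- data.frame(
        tag_class = factor(res$class,
                           levels = c("primary", "processed", "untagged",
                                      "ambiguous")),
        trimmed = trimmed,
        stringsAsFactors = FALSE)
    attr(out, "short_reads") <- res$short
    out
}

#' Demultiplex a tagRNA-seq FASTQ by 5' tag
#'
#' Sorts reads into independent primary / processed / untagged FASTQ files,
#' trimming tag bases (and their qualities, in register) from tagged reads.
#' Every input read is written to exactly one output file; ambiguous reads
#' (possible only with a relaxed tag pair) go to a fourth `.ambiguous` file
#' and are meant to be excluded from downstream tracks, since their
#' misclassification would corrupt the primary/processed contrast that
#' defines TSS calls.
#'
#' @param fastq path to the input FASTQ (gzip-transparent).
#' @param tags a [TagSpec-class].
#' @param outPrefix path prefix for outputs; files are named
#'   `<outPrefix>.primary.fastq`, `.processed.fastq`, `.untagged.fastq`
#'   (and `.ambiguous.fastq` when needed).
#' @return A list with `counts` (named integer vector over the four
#'   classes, summing to the input read count), `files` (paths written) and
#'   `short_reads`.
#' @seealso [classifyReads()]
#' @export
demuxFastq <- function(fastq, tags = tagSpec(), outPrefix = "demux") {
    reads <- readFastq(fastq)
    cls <- classifyReads(sread(reads), tags)
    k <- nchar(tags@primary)
    counts <- table(cls$tag_class)
    files <- character()
    for (cl in c("primary", "processed", "untagged", "ambiguous")) {
        sel <- cls$tag_class == cl
        if (cl == "ambiguous" && !any(sel)) next
        out <- reads[sel]
        if (cl %in% c("primary", "processed") && length(out) > 0L)
            out <- narrow(out, start = k + 1L)
        path <- paste0(outPrefix, ".", cl, ".fastq")
        writeFastq(out, path, mode = "w", compress = FALSE)
        files[cl] <- path
    }
    list(counts = setNames(as.integer(counts), names(counts)),
         files = files,
         short_reads = attr(cls, "short_reads"))
}
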