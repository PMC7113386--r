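## Core S4 containers: tag specification and per-nucleotide genomic tracks.

.DNA_ALPHABET <- c("A", "C", "G", "T")

.hamming <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' TagSpec: the 5'-tag pair used for demultiplexing
#'
#' Holds the primary-transcript tag (ligated after polyphosphatase
#' conversion of 5'-triphosphate ends), the processed-transcript tag
#' (ligated to pre-existing 5'-monophosphate ends), and the number of
#' mismatches tolerated when matching a read's 5' prefix. Validity requires
#' equal-length ACGT tags whose Hamming distance exceeds twice
#' `maxMismatch`, so that no read prefix can match both tags and
#' classification is unambiguous.
#'
#' @slot primary character; the primary-transcript tag sequence.
#' @slot processed character; the processed-transcript tag sequence.
#' @slot maxMismatch integer; mismatches tolerated in the tag prefix.
#'
#' @seealso [tagSpec()], [classifyReads()], [demuxFastq()]
#' @exportClass TagSpec
setClass("TagSpec", representation(
    primary = "character",
    processed = "character",
    maxMismatch = "integer"
))

setValidity("TagSpec", function(object) {
    p <- object@primary
    q <- object@processed
    m <- object@maxMismatch
    msg <- character()
    if (length(p) != 1L || length(q) != 1L || length(m) != 1L)
        msg <- c(msg, "primary, processed and maxMismatch must have length 1")
    else {
        if (nchar(p) == 0L || nchar(q) == 0L)
            msg <- c(msg, "tags must be non-empty")
        if (nchar(p) != nchar(q))
            msg <- c(msg, "tags must have equal length")
        if (!all(strsplit(paste0(p, q), "")[[1]] %in% .DNA_ALPHABET))
            msg <- c(msg, "tags must be over the alphabet {A,C,G,T}")
        if (is.na(m) || m < 0L)
            msg <- c(msg, "maxMismatch must be a non-negative integer")
        else if (nchar(p) == nchar(q) && .hamming(p, q) <= 2L * m)
            msg <- c(msg, sprintf(
                "Hamming distance between tags (%d) must exceed 2*maxMismatch (%d) for unambiguous classification",
                .hamming(p, q), 2L * m))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TagSpec
#'
#' Defaults are the tag pair used in tagRNA-seq library construction:
#' `TAATGCGC` marks primary transcripts (5'-triphosphate ends converted by
#' RNA 5' polyphosphatase) and `CTGAAGCT` marks processed transcripts
#' (native 5'-monophosphate ends).
#'
#' @param primary primary-transcript tag sequence.
#' @param processed processed-transcript tag sequence.
#' @param maxMismatch mismatches tolerated when matching a read prefix to a
#'   tag. The default 0 (exact matching) is the conservative choice; any
#'   value is accepted as long as the two tags stay unambiguous.
#' @return A [TagSpec-class] object.
#' @examples
#' tagSpec()
#' tagSpec(maxMismatch = 1)
#' @export
tagSpec <- function(primary = "TAATGCGC", processed = "CTGAAGCT",
                    maxMismatch = 0L) {
    new("TagSpec", primary = toupper(primary), processed = toupper(processed),
        maxMismatch = as.integer(maxMismatch))
}

setMethod("show", "TagSpec", function(object) {
    cat("TagSpec\n",
        "  primary tag:   ", object@primary, "\n",
        "  processed tag: ", object@processed, "\n",
        "  max mismatch:  ", object@maxMismatch, "\n", sep = "")
})

.TRACK_CLASSES <- c("primary", "processed", "net")

#' StartTrack: strand-specific per-nucleotide 5'-end counts
#'
#' The unit the TSS-calling method operates on: for one sample and one
#' transcript class ("primary" or "processed"; "net" after subtraction),
#' two vectors of genome length hold the number of accepted read 5' ends at
#' each position on each strand. Values are integer counts before
#' normalization and non-negative reals afterwards; "net" tracks may hold
#' negative values only when subtraction was run unclamped.
#'
#' @slot sample character; sample identifier.
#' @slot txClass character; one of "primary", "processed", "net".
#' @slot plus numeric; per-position counts on the + strand.
#' @slot minus numeric; per-position counts on the - strand.
#'
#' @seealso [startTrack()], [buildStartTrack()], [subtractTracks()]
#' @exportClass StartTrack
setClass("StartTrack", representation(
    sample = "character",
    txClass = "character",
    plus = "numeric",
    minus = "numeric"
))

setValidity("StartTrack", function(object) {
    msg <- character()
    if (length(object@sample) != 1L || length(object@txClass) != 1L)
        msg <- c(msg, "sample and class must have length 1")
    if (!object@txClass %in% .TRACK_CLASSES)
        msg <- c(msg, sprintf("class must be one of %s",
                              paste(.TRACK_CLASSES, collapse = ", ")))
    if (length(object@plus) != length(object@minus))
        msg <- c(msg, "plus and minus vectors must have equal length")
    if (anyNA(object@plus) || anyNA(object@minus))
        msg <- c(msg, "track values must not be NA")
    if (object@txClass %in% c("primary", "processed") &&
        (any(object@plus < 0) || any(object@minus < 0)))
        msg <- c(msg, "primary/processed track values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a StartTrack
#'
#' @param plus,minus numeric vectors of per-position 5'-end counts, one per
#'   strand, each of genome length.
#' @param class transcript class: "primary", "processed" or "net".
#' @param sample sample identifier.
#' @return A [StartTrack-class] object.
#' @export
startTrack <- function(plus, minus, class = "primary", sample = "sample1") {
    new("StartTrack", sample = sample, txClass = class,
        plus = as.numeric(plus), minus = as.numeric(minus))
}

setMethod("show", "StartTrack", function(object) {
    cat("StartTrack [", object@sample, ", ", object@txClass, "]\n",
        "  genome length: ", length(object@plus), "\n",
        "  mass (+/-):    ", sum(object@plus), " / ", sum(object@minus), "\n",
        "  nonzero (+/-): ", sum(object@plus != 0), " / ",
        sum(object@minus != 0), "\n", sep = "")
})

#' DepthTrack: per-nucleotide read depth
#'
#' Strand-combined coverage: `depth[p]` is the number of alignments whose
#' reference span covers position `p`.
#'
#' @slot sample character; sample identifier.
#' @slot depth numeric; per-position depth of genome length.
#'
#' @seealso [buildDepthTrack()]
#' @exportClass DepthTrack
setClass("DepthTrack", representation(
    sample = "character",
    depth = "numeric"
))

setValidity("DepthTrack", function(object) {
    msg <- character()
    if (length(object@sample) != 1L)
        msg <- c(msg, "sample must have length 1")
    if (anyNA(object@depth) || any(object@depth < 0))
        msg <- c(msg, "depth must be non-negative and non-NA")
    if (length(msg)) msg else TRUE
})

#' Construct a DepthTrack
#'
#' @param depth numeric vector of per-position depth.
#' @param sample sample identifier.
#' @return A [DepthTrack-class] object.
#' @export
depthTrack <- function(depth, sample = "sample1") {
    new("DepthTrack", sample = sample, depth = as.numeric(depth))
}

setMethod("show", "DepthTrack", function(object) {
    cat("DepthTrack [", object@sample, "]\n",
        "  genome length: ", length(object@depth), "\n",
        "  total depth:   ", sum(object@depth), "\n", sep = "")
})
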