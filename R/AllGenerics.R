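#' Accessors for track objects
#'
#' `genomeLength()` returns the number of positions a track spans;
#' `sampleId()` the sample identifier; `trackClass()` the transcript class
#' of a [StartTrack-class]; `trackValues()` the per-position value vector
#' (for a StartTrack, of the requested strand).
#'
#' @param x a [StartTrack-class] or [DepthTrack-class].
#' @param strand `"+"` or `"-"` (StartTrack only).
#' @return `genomeLength()` an integer; `sampleId()` and `trackClass()`
#'   character scalars; `trackValues()` a numeric vector.
#' @examples
#' tr <- startTrack(c(0, 2, 0), c(1, 0, 0))
#' genomeLength(tr)
#' trackValues(tr, "+")
#' @name track-accessors
NULL

#' @rdname track-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname track-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname track-accessors
#' @export
setGeneric("trackClass", function(x) standardGeneric("trackClass"))

#' @rdname track-accessors
#' @export
setGeneric("trackValues", function(x, strand = "+") standardGeneric("trackValues"))

#' @rdname track-accessors
setMethod("genomeLength", "StartTrack", function(x) length(x@plus))

#' @rdname track-accessors
setMethod("genomeLength", "DepthTrack", function(x) length(x@depth))

#' @rdname track-accessors
setMethod("sampleId", "StartTrack", function(x) x@sample)

#' @rdname track-accessors
setMethod("sampleId", "DepthTrack", function(x) x@sample)

#' @rdname track-accessors
setMethod("trackClass", "StartTrack", function(x) x@txClass)

#' @rdname track-accessors
setMethod("trackValues", "StartTrack", function(x, strand = "+") {
    strand <- match.arg(strand, c("+", "-"))
    if (strand == "+") x@plus else x@minus
})

#' @rdname track-accessors
setMethod("trackValues", "DepthTrack", function(x, strand = "+") x@depth)
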