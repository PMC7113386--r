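## Wiggle / bedGraph writers and readers.
##
## Written in-package (rather than via a converter) because the package
## contract is an exact write->read round trip: values are serialized with
## %.17g, which preserves IEEE doubles bit-for-bit. Coordinates are 1-based
## inclusive internally and in wiggle; bedGraph is converted to 0-based
## half-open at the boundary, per the two formats' own standards.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read per-position tracks as wiggle or bedGraph
#'
#' `writeWig()` writes the nonzero positions of a numeric vector as a
#' 1-based `variableStep` wiggle (zero runs omitted); `writeBedGraph()`
#' writes 0-based half-open bedGraph intervals, merging runs of equal
#' nonzero values. `readWig()` / `readBedGraph()` invert them exactly.
#' Values survive the round trip bit-for-bit.
#'
#' @param values numeric vector of per-position values (index = 1-based
#'   genomic position).
#' @param path output (input) file path.
#' @param chrom chromosome name written to the headers.
#' @param genomeLength length of the vector to reconstruct on read.
#' @return Writers return `path` invisibly; readers return a numeric
#'   vector of length `genomeLength`.
#' @examples
#' v <- numeric(50); v[c(10, 11, 40)] <- c(2, 2, 1.5)
#' f <- tempfile(fileext = ".wig")
#' writeWig(v, f)
#' identical(readWig(f, 50), v)
#' @name track-io
NULL

#' @rdname track-io
#' @export
writeWig <- function(values, path, chrom = "chr") {
    nz <- which(values != 0)
    lines <- c(sprintf("track type=wiggle_0 name=\"%s\"",
                       basename(path)),
               sprintf("variableStep chrom=%s span=1", chrom))
    if (length(nz))
        lines <- c(lines, paste(nz, .fmtNum(values[nz])))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname track-io
#' @export
readWig <- function(path, genomeLength) {
    lines <- readLines(path)
    out <- numeric(genomeLength)
    mode <- NULL
    fsPos <- fsStep <- NA_integer_
    for (ln in lines) {
        if (grepl("^track", ln)) next
        if (grepl("^variableStep", ln)) { mode <- "v"; next }
        if (grepl("^fixedStep", ln)) {
            mode <- "f"
            fsPos <- as.integer(sub(".*start=([0-9]+).*", "\\1", ln))
            fsStep <- if (grepl("step=", ln))
                as.integer(sub(".*step=([0-9]+).*", "\\1", ln)) else 1L
            next
        }
        if (!nzchar(ln)) next
        if (is.null(mode)) stop("wiggle data before a step declaration")
        if (mode == "v") {
            f <- strsplit(trimws(ln), "[ \t]+")[[1]]
            out[as.integer(f[1L])] <- as.numeric(f[2L])
        } else {
            out[fsPos] <- as.numeric(trimws(ln))
            fsPos <- fsPos + fsStep
        }
    }
    out
}

#' @rdname track-io
#' @export
writeBedGraph <- function(values, path, chrom = "chr") {
    r <- rle(values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    lines <- sprintf("track type=bedGraph name=\"%s\"", basename(path))
    if (any(keep))
        lines <- c(lines, paste(chrom, starts[keep] - 1L, ends[keep],
                                .fmtNum(r$values[keep]), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname track-io
#' @export
readBedGraph <- function(path, genomeLength) {
    lines <- readLines(path)
    lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
    out <- numeric(genomeLength)
    for (ln in lines) {
        f <- strsplit(ln, "\t")[[1]]
        out[(as.integer(f[2L]) + 1L):as.integer(f[3L])] <- as.numeric(f[4L])
    }
    out
}

#' Write / read a StartTrack as a pair of strand files
#'
#' File naming follows `<sample>.<class>.<strand>.wig` with strand tokens
#' `plus` / `minus` (filesystem-safe stand-ins for `+` / `-`).
#'
#' @param track a [StartTrack-class].
#' @param dir output directory.
#' @param format "wig" or "bedGraph".
#' @param chrom chromosome name for the headers.
#' @param plusPath,minusPath the two strand files to read back.
#' @param genomeLength,class,sample reconstruction parameters.
#' @return `writeStartTrack()` the two paths, invisibly; `readStartTrack()`
#'   a [StartTrack-class].
#' @export
writeStartTrack <- function(track, dir = ".", format = c("wig", "bedGraph"),
                            chrom = "chr") {
    format <- match.arg(format)
    ext <- if (format == "wig") "wig" else "bedGraph"
    wfun <- if (format == "wig") writeWig else writeBedGraph
    paths <- file.path(dir, sprintf("%s.%s.%s.%s", sampleId(track),
                                    trackClass(track), c("plus", "minus"),
                                    ext))
    wfun(trackValues(track, "+"), paths[1L], chrom)
    wfun(trackValues(track, "-"), paths[2L], chrom)
    invisible(paths)
}

#' @rdname writeStartTrack
#' @export
readStartTrack <- function(plusPath, minusPath, genomeLength,
                           class = "primary", sample = "sample1",
                           format = c("wig", "bedGraph")) {
    format <- match.arg(format)
    rfun <- if (format == "wig") readWig else readBedGraph
    startTrack(rfun(plusPath, genomeLength), rfun(minusPath, genomeLength),
               class = class, sample = sample)
}

#' Write / read gene annotation as GFF3
#'
#' Thin wrappers over rtracklayer that preserve the `gene_id`, `role` and
#' `precursor` metadata columns used throughout the package.
#'
#' @param genes a [GenomicRanges::GRanges] with a `gene_id` column.
#' @param path GFF3 file path.
#' @param chrom chromosome name (read side: used to set seqnames).
#' @return `readGenesGff3()` returns the annotation GRanges.
#' @export
writeGenesGff3 <- function(genes, path) {
    out <- genes
    mcols(out)$type <- "gene"
    mcols(out)$ID <- mcols(genes)$gene_id
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' @rdname writeGenesGff3
#' @export
readGenesGff3 <- function(path, chrom = NULL) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[mcols(gr)$type == "gene"]
    mcols(gr) <- DataFrame(
        gene_id = as.character(mcols(gr)$ID),
        role = if (!is.null(mcols(gr)$role)) as.character(mcols(gr)$role)
               else NA_character_,
        precursor = if (!is.null(mcols(gr)$precursor))
            as.logical(mcols(gr)$precursor) else FALSE)
    gr
}
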