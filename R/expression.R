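## Gene-level quantification: counts, RPKM, TPM and genome-wide ranking.

#' Count reads per gene
#'
#' A read is assigned to a gene when its 5'-most aligned base lies within
#' the gene span and the strands match. Assignment by the 5' base is
#' deterministic and never double-counts a read even when genes overlap
#' (overlaps are resolved to the first gene in annotation order); an
#' alternative `countMode = "span-overlap"` counts a read for every gene
#' its full reference span overlaps.
#'
#' @param aln a [GenomicAlignments::GAlignments], or (for the default mode)
#'   a width-1 [GenomicRanges::GRanges] of 5' positions.
#' @param genes annotation [GenomicRanges::GRanges] with a `gene_id`
#'   column.
#' @param genomeLength optional; when given, genes extending outside
#'   `[1, genomeLength]` raise an error.
#' @param countMode `"five-prime"` (default) or `"span-overlap"`.
#' @param max5pSoftclip passed to [fivePrimePositions()] for GAlignments
#'   input.
#' @return A named integer vector of counts (names = `gene_id`), with
#'   attribute `intergenic` counting reads assigned to no gene.
#' @export
countReadsPerGene <- function(aln, genes, genomeLength = NULL,
                              countMode = c("five-prime", "span-overlap"),
                              max5pSoftclip = 3L) {
    countMode <- match.arg(countMode)
    if (!is.null(genomeLength) &&
        length(genes) && (min(start(genes)) < 1L ||
                          max(end(genes)) > genomeLength))
        stop("feature outside genome [1,", genomeLength, "]")
    ids <- mcols(genes)$gene_id
    if (is.null(ids)) stop("genes must carry a gene_id column")
    if (countMode == "span-overlap") {
        if (!is(aln, "GAlignments"))
            stop("span-overlap mode needs a GAlignments input")
        spans <- GRanges(seqnames(aln), IRanges(start(aln), end(aln)),
                         strand = strand(aln))
        counts <- countOverlaps(genes, spans)
        n <- length(aln)
        assigned <- countOverlaps(spans, genes) > 0
        out <- setNames(as.integer(counts), ids)
        attr(out, "intergenic") <- sum(!assigned)
        return(out)
    }
    sites <- if (is(aln, "GAlignments"))
        fivePrimePositions(aln, max5pSoftclip) else aln
    hit <- findOverlaps(sites, genes, select = "first")
    tab <- tabulate(hit[!is.na(hit)], nbins = length(genes))
    out <- setNames(as.integer(tab), ids)
    attr(out, "intergenic") <- sum(is.na(hit))
    out
}

#' RPKM: reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length/1e3) * (totalMapped/1e6))`.
#'
#' @param count read count(s) for the gene(s).
#' @param geneLength gene length(s) in nt; must be positive.
#' @param totalMapped total mapped reads in the library (all accepted
#'   alignments, intergenic included); must be positive.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' rpkm(7, 2500, 3.2e6)  # 0.875
#' @export
rpkm <- function(count, geneLength, totalMapped) {
    if (any(totalMapped <= 0)) stop("totalMapped must be positive")
    if (any(geneLength <= 0)) stop("geneLength must be positive")
    count / ((geneLength / 1e3) * (totalMapped / 1e6))
}

#' TPM: transcripts per million
#'
#' Length-normalized rates `count/length` rescaled to sum to 1e6. An
#' all-zero count vector returns all zeros (the degenerate case of an
#' empty library).
#'
#' @param counts read counts per gene.
#' @param geneLengths gene lengths in nt; must be positive.
#' @return Numeric TPM vector summing to 1e6 (or all zeros).
#' @examples
#' tpm(c(10, 10), c(1000, 2000))
#' @export
tpm <- function(counts, geneLengths) {
    if (any(geneLengths <= 0)) stop("geneLengths must be positive")
    rate <- counts / geneLengths
    s <- sum(rate)
    if (s == 0) return(rep(0, length(counts)))
    1e6 * rate / s
}

#' Rank genes by TPM
#'
#' Descending order; tied values all receive the minimum rank of the tied
#' block (a tie for 4th place reports both genes at rank 4).
#'
#' @param tpmValues numeric (optionally named) TPM vector.
#' @return Integer ranks, named as the input.
#' @examples
#' rankGenes(c(a = 5, b = 10, c = 1))  # a 2, b 1, c 3
#' @export
rankGenes <- function(tpmValues) {
    if (length(tpmValues) == 0L) return(setNames(integer(0),
                                                 names(tpmValues)))
    r <- rank(-tpmValues, ties.method = "min")
    setNames(as.integer(r), names(tpmValues))
}

#' Full expression table for one sample
#'
#' Gene counts (5'-base assignment), RPKM against the total accepted
#' alignment count (intergenic reads included in the denominator), TPM and
#' genome-wide rank, as one tidy table.
#'
#' @inheritParams countReadsPerGene
#' @return A data.frame with columns `gene`, `count`, `length`, `rpkm`,
#'   `tpm`, `rank`.
#' @export
expressionTable <- function(aln, genes, genomeLength = NULL,
                            max5pSoftclip = 3L) {
    counts <- countReadsPerGene(aln, genes, genomeLength,
                                max5pSoftclip = max5pSoftclip)
    total <- sum(counts) + attr(counts, "intergenic")
    lens <- width(genes)
    tp <- tpm(as.numeric(counts), lens)
    data.frame(gene = names(counts),
               count = as.integer(counts),
               length = lens,
               rpkm = rpkm(as.numeric(counts), lens, total),
               tpm = tp,
               rank = rankGenes(setNames(tp, names(counts))),
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' @rdname expressionTable
#' @param x an expression table.
#' @param path output TSV path.
#' @export
writeExpressionTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
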