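## The core computation: normalize start tracks across samples, subtract
## processed from primary signal ("wig minus wig"), call TSS peaks and
## classify them against the annotation.

## Rank-average quantile normalization of a samples-in-columns matrix.
## Each position receives the cross-sample mean of the order statistics at
## its rank; a tied block receives the mean of those means over the block.
.quantileNormalizeMatrix <- function(M) {
    if (ncol(M) == 1L) return(M)
    S <- apply(M, 2L, sort)
    m <- rowMeans(S)
    cm <- c(0, cumsum(m))
    out <- M
    for (j in seq_len(ncol(M))) {
        x <- M[, j]
        o <- order(x)
        r <- rle(x[o])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        blockMean <- (cm[ends + 1L] - cm[starts]) / r$lengths
        out[, j] <- blockMean[match(x, r$values)]
    }
    out
}

#' Quantile-normalize start tracks across samples
#'
#' Removes sequencing-depth bias between samples by rank-average quantile
#' normalization, applied per strand across all samples of one transcript
#' class: each sample's value vector is sorted, the order statistics are
#' averaged across samples at each sort index, and every position is
#' assigned the mean for its rank (tied ranks receive the average of the
#' means over the tied block). A single track is returned unchanged.
#' Normalization runs on the full-length genome vectors, zeros included;
#' normalizing only nonzero positions would give different results.
#'
#' @param tracks list of [StartTrack-class] objects of one class, equal
#'   genome length.
#' @return A list of normalized [StartTrack-class] objects (same samples,
#'   same class).
#' @examples
#' a <- startTrack(c(1, 2, 3), numeric(3), sample = "s1")
#' b <- startTrack(c(4, 5, 6), numeric(3), sample = "s2")
#' trackValues(quantileNormalizeTracks(list(a, b))[[1]], "+")
#' @export
quantileNormalizeTracks <- function(tracks) {
    stopifnot(length(tracks) >= 1L)
    lens <- vapply(tracks, genomeLength, integer(1))
    if (length(unique(lens)) != 1L)
        stop("tracks must have equal genome length")
    cls <- unique(vapply(tracks, trackClass, character(1)))
    if (length(cls) != 1L)
        stop("tracks must share one transcript class")
    if (length(tracks) == 1L) return(tracks)
    P <- .quantileNormalizeMatrix(vapply(tracks, trackValues, numeric(lens[1]),
                                         strand = "+"))
    M <- .quantileNormalizeMatrix(vapply(tracks, trackValues, numeric(lens[1]),
                                         strand = "-"))
    lapply(seq_along(tracks), function(i)
        startTrack(P[, i], M[, i], class = cls,
                   sample = sampleId(tracks[[i]])))
}

#' Subtract processed from primary signal ("wig minus wig")
#'
#' The discriminating step of the method: per position and strand,
#' `net = primary - processed`, clamped at zero by default since negative
#' "primary" signal carries no TSS meaning. Regions surviving in the net
#' track are the candidate true TSSs.
#'
#' @param primary,processed [StartTrack-class] objects from the same
#'   sample, equal genome length.
#' @param clamp clamp negative differences to zero (default `TRUE`).
#' @return A [StartTrack-class] of class `"net"`.
#' @export
subtractTracks <- function(primary, processed, clamp = TRUE) {
    if (genomeLength(primary) != genomeLength(processed))
        stop("track length mismatch")
    if (sampleId(primary) != sampleId(processed))
        stop("tracks come from different samples")
    p <- trackValues(primary, "+") - trackValues(processed, "+")
    m <- trackValues(primary, "-") - trackValues(processed, "-")
    if (clamp) { p <- pmax(0, p); m <- pmax(0, m) }
    startTrack(p, m, class = "net", sample = sampleId(primary))
}

.callStrand <- function(v, strandChar, minCount, mergeWindow) {
    idx <- which(v >= minCount)
    if (!length(idx))
        return(data.frame(position = integer(0), strand = character(0),
                          score = numeric(0)))
    grp <- cumsum(c(1L, diff(idx) > mergeWindow))
    reps <- vapply(split(idx, grp), function(b) b[which.max(v[b])],
                   integer(1))
    data.frame(position = unname(reps), strand = strandChar,
               score = v[reps])
}

#' Call TSS peaks from a net start track
#'
#' Positions with net signal at or above `minCount` are candidates;
#' same-strand candidates within `mergeWindow` nt of each other merge into
#' one call at the maximum-signal position (ties resolve to the smallest
#' coordinate). The score is the net value at the representative position.
#'
#' @param net a [StartTrack-class] of class `"net"` (from
#'   [subtractTracks()]).
#' @param minCount minimum net signal (normalized units); must be > 0.
#' @param mergeWindow merge distance in nt (default 3).
#' @param primary,processed optional raw (pre-normalization) tracks; when
#'   given, `raw_primary` / `raw_processed` columns report the original
#'   counts at each call.
#' @return A width-1 [GenomicRanges::GRanges] with `tss_id` and `score`
#'   columns (plus raw counts if requested), sorted by coordinate.
#' @export
callTss <- function(net, minCount = 10, mergeWindow = 3L,
                    primary = NULL, processed = NULL) {
    if (minCount <= 0) stop("minCount must be positive")
    calls <- rbind(
        .callStrand(trackValues(net, "+"), "+", minCount, mergeWindow),
        .callStrand(trackValues(net, "-"), "-", minCount, mergeWindow))
    calls <- calls[order(calls$position), , drop = FALSE]
    gr <- GRanges(rep("chr", nrow(calls)),
                  IRanges(calls$position, width = 1L),
                  strand = calls$strand)
    mcols(gr)$tss_id <- sprintf("tss_%04d", seq_len(nrow(calls)))
    mcols(gr)$score <- calls$score
    if (!is.null(primary))
        mcols(gr)$raw_primary <- ifelse(calls$strand == "+",
            trackValues(primary, "+")[calls$position],
            trackValues(primary, "-")[calls$position])
    if (!is.null(processed))
        mcols(gr)$raw_processed <- ifelse(calls$strand == "+",
            trackValues(processed, "+")[calls$position],
            trackValues(processed, "-")[calls$position])
    gr
}

#' Classify TSS calls against the gene annotation
#'
#' Each call is assigned to the nearest same-strand gene whose start codon
#' lies downstream within `maxUpstream` nt. Categories: `gene_tss` for a
#' plain assigned call; `internal` when the call also lies inside another
#' same-strand gene's span (an intragenic TSS, like a precursor gene's
#' dedicated start inside the preceding gene); `antisense` when no
#' same-strand assignment exists but the call falls within an
#' opposite-strand gene; `orphan` otherwise. The 5'UTR length counts the
#' TSS base as transcribed: `utr = gene start - position` on `+`,
#' `position - gene end` on `-` (a TSS at the start codon has UTR 0).
#' Leadered classes: `leaderless` below `leaderlessMax`, `extended_leadered`
#' above `extendedMin`, `leadered` between.
#'
#' @param calls [GenomicRanges::GRanges] from [callTss()].
#' @param genes annotation [GenomicRanges::GRanges] with `gene_id`.
#' @param genomeLength genome length (bounds check).
#' @param maxUpstream maximum TSS-to-start-codon distance (default 500 nt,
#'   which accommodates long extended-leadered 5'UTRs).
#' @param leaderlessMax UTRs strictly below this are leaderless (default
#'   10 nt).
#' @param extendedMin UTRs strictly above this are extended-leadered
#'   (default 100 nt, the lower bound of the usual 100-150 nt convention).
#' @return The calls with added columns `gene`, `utr_length`, `category`,
#'   `leadered_class`.
#' @export
classifyTss <- function(calls, genes, genomeLength = NULL,
                        maxUpstream = 500L, leaderlessMax = 10L,
                        extendedMin = 100L) {
    ids <- mcols(genes)$gene_id
    if (is.null(ids)) stop("genes must carry a gene_id column")
    gStart <- start(genes); gEnd <- end(genes)
    gStr <- as.character(strand(genes))
    n <- length(calls)
    gene <- rep(NA_character_, n)
    utr <- rep(NA_integer_, n)
    category <- rep("orphan", n)
    pos <- start(calls)
    str <- as.character(strand(calls))
    for (i in seq_len(n)) {
        same <- gStr == str[i]
        d <- if (str[i] == "+") gStart - pos[i] else pos[i] - gEnd
        cand <- which(same & d >= 0L & d <= maxUpstream)
        within <- gStart <= pos[i] & gEnd >= pos[i]
        if (length(cand)) {
            pick <- cand[which.min(d[cand])]
            gene[i] <- ids[pick]
            utr[i] <- d[pick]
            inOther <- any(within & same & seq_along(ids) != pick)
            category[i] <- if (inOther) "internal" else "gene_tss"
        } else if (any(within & !same)) {
            category[i] <- "antisense"
        }
    }
    mcols(calls)$gene <- gene
    mcols(calls)$utr_length <- utr
    mcols(calls)$category <- factor(category,
        levels = c("gene_tss", "internal", "antisense", "orphan"))
    lc <- rep(NA_character_, n)
    ok <- !is.na(utr)
    lc[ok] <- ifelse(utr[ok] < leaderlessMax, "leaderless",
                     ifelse(utr[ok] > extendedMin, "extended_leadered",
                            "leadered"))
    mcols(calls)$leadered_class <- factor(lc,
        levels = c("leaderless", "leadered", "extended_leadered"))
    calls
}

#' Scan for sigma-70 promoter boxes upstream of a TSS
#'
#' Exhaustive search of -35/-10 hexamer pairs in the 60 nt upstream of the
#' TSS on its strand: the -10 box must end `gapRange` nt before the TSS
#' and the spacer between the boxes must lie in `spacerRange`. Each
#' placement is scored by its total mismatches to the consensus
#' (`TTGACA` / `TATAAT`); the best placement (fewest mismatches, ties to
#' the spacer closest to 17 nt, then to the smaller gap) is returned, or
#' `NULL` when the best exceeds `maxMismatches`. This is a plain consensus
#' scanner for annotation convenience, not a promoter-strength predictor.
#'
#' @param genome a [Biostrings::DNAStringSet] (first sequence used) or
#'   [Biostrings::DNAString].
#' @param position,strand TSS coordinate and strand.
#' @param gapRange allowed nt between the -10 box 3' end and the TSS
#'   (default 4-9).
#' @param spacerRange allowed nt between the boxes (default 15-19).
#' @param maxMismatches report nothing above this score (default 8).
#' @param consensus35,consensus10 consensus hexamers.
#' @return A one-row data.frame (`minus35`, `minus35_pos`,
#'   `minus35_mismatches`, `minus10`, `minus10_pos`,
#'   `minus10_mismatches`, `spacer`, `gap`, `mismatches`) or `NULL`.
#'   Positions are the genomic coordinate of each hexamer's 5' base on the
#'   TSS strand.
#' @export
promoterBoxScan <- function(genome, position, strand = "+",
                            gapRange = c(4L, 9L), spacerRange = c(15L, 19L),
                            maxMismatches = 8L,
                            consensus35 = "TTGACA", consensus10 = "TATAAT") {
    if (is(genome, "DNAStringSet")) genome <- genome[[1L]]
    L <- length(genome)
    win <- 60L
    if (strand == "+") {
        if (position - win < 1L) {
            warning("insufficient upstream sequence for promoter scan")
            return(NULL)
        }
        up <- as.character(subseq(genome, position - win, position - 1L))
    } else {
        if (position + win > L) {
            warning("insufficient upstream sequence for promoter scan")
            return(NULL)
        }
        up <- as.character(reverseComplement(
            subseq(genome, position + 1L, position + win)))
    }
    hex <- function(i) substr(up, i, i + 5L)
    mm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    best <- NULL
    for (gap in seq(gapRange[1L], gapRange[2L])) {
        s10 <- win - gap - 5L   # window index of -10 start
        if (s10 < 1L) next
        m10 <- mm(hex(s10), consensus10)
        for (spacer in seq(spacerRange[1L], spacerRange[2L])) {
            s35 <- s10 - spacer - 6L
            if (s35 < 1L) next
            m35 <- mm(hex(s35), consensus35)
            key <- c(m10 + m35, abs(spacer - 17L), gap)
            if (is.null(best) ||
                key[1L] < best$key[1L] ||
                (key[1L] == best$key[1L] && key[2L] < best$key[2L]) ||
                (key[1L] == best$key[1L] && key[2L] == best$key[2L] &&
                 key[3L] < best$key[3L])) {
                best <- list(key = key, s10 = s10, s35 = s35, m10 = m10,
                             m35 = m35, spacer = spacer, gap = gap)
            }
        }
    }
    if (is.null(best) || best$key[1L] > maxMismatches) return(NULL)
    toGenomic <- function(i)
        if (strand == "+") position - win - 1L + i else position + win + 1L - i
    data.frame(minus35 = hex(best$s35),
               minus35_pos = toGenomic(best$s35),
               minus35_mismatches = best$m35,
               minus10 = hex(best$s10),
               minus10_pos = toGenomic(best$s10),
               minus10_mismatches = best$m10,
               spacer = best$spacer,
               gap = best$gap,
               mismatches = best$m35 + best$m10,
               stringsAsFactors = FALSE)
}
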