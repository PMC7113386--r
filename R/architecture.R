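## Higher-level architecture: transcription-unit inference with attenuator
## annotation, precursor-gene TSS reports, and the DNA-affinity-capture
## candidate filter.

.asTerminatorFrame <- function(terminators) {
    if (is.null(terminators) || NROW(terminators) == 0L)
        return(data.frame(term_id = character(0), position = integer(0),
                          strand = character(0), delta_g = numeric(0),
                          stringsAsFactors = FALSE))
    terminators <- as.data.frame(terminators)
    if (is.null(terminators$term_id))
        terminators$term_id <- sprintf("term_%02d", seq_len(nrow(terminators)))
    if (any(terminators$delta_g >= 0))
        stop("terminator delta_G must be negative (kcal/mol)")
    terminators
}

#' Infer transcription units from genes, TSS calls and terminators
#'
#' Maximal runs of adjacent same-strand genes are split at (a) strand
#' changes, (b) intrinsic terminators at or below `splitThreshold` lying
#' between consecutive genes, and (c) intergenic gaps wider than `maxGap`.
#' Terminators between genes that remain joined (their free energy is
#' above the split threshold, i.e. they are imperfect) are annotated as
#' attenuators of the unit: they dampen but do not abolish downstream
#' transcription. An internal TSS never splits a unit; it is recorded on
#' the unit instead, which is how a precursor gene inside an operon gets
#' its dedicated start without breaking co-transcription. A terminator on
#' the unit's strand within `maxGap` nt downstream of its last gene is
#' recorded as the terminal terminator.
#'
#' @param genes annotation [GenomicRanges::GRanges] with `gene_id`, sorted
#'   by start coordinate (unsorted input errors).
#' @param tssCalls classified calls from [classifyTss()] (their `gene`
#'   column links them to units); may be `NULL`.
#' @param terminators data.frame with columns `position`, `strand`,
#'   `delta_g` (negative, kcal/mol) and optionally `term_id`; may be
#'   `NULL`.
#' @param splitThreshold terminators with `delta_g` at or below this split
#'   units (default -15 kcal/mol).
#' @param maxGap maximum intergenic gap within a unit, and the window for
#'   terminal-terminator search (default 300 nt).
#' @return A [GenomicRanges::GRanges] with one range per unit and columns
#'   `tu_id`, `gene_ids` (CharacterList, genomic order), `n_genes`,
#'   `tss_ids` (CharacterList), `terminator`, `attenuators`
#'   (CharacterList) and `span` (nt, driving TSSs included).
#' @export
inferTranscriptionUnits <- function(genes, tssCalls = NULL,
                                    terminators = NULL,
                                    splitThreshold = -15, maxGap = 300L) {
    ids <- mcols(genes)$gene_id
    if (is.null(ids)) stop("genes must carry a gene_id column")
    if (is.unsorted(start(genes)))
        stop("genes must be sorted by start coordinate")
    term <- .asTerminatorFrame(terminators)
    n <- length(genes)
    gStart <- start(genes); gEnd <- end(genes)
    gStr <- as.character(strand(genes))

    splitAfter <- logical(max(n - 1L, 0L))
    attenAfter <- vector("list", max(n - 1L, 0L))
    for (i in seq_len(max(n - 1L, 0L))) {
        if (gStr[i] != gStr[i + 1L]) { splitAfter[i] <- TRUE; next }
        gap <- gStart[i + 1L] - gEnd[i] - 1L
        between <- term$strand == gStr[i] &
            term$position > gEnd[i] & term$position < gStart[i + 1L]
        strong <- between & term$delta_g <= splitThreshold
        if (any(strong) || gap > maxGap) { splitAfter[i] <- TRUE; next }
        attenAfter[[i]] <- term$term_id[between]
    }
    tuIdx <- cumsum(c(1L, as.integer(splitAfter)))

    callGene <- if (!is.null(tssCalls)) mcols(tssCalls)$gene else NULL
    callId <- if (!is.null(tssCalls)) mcols(tssCalls)$tss_id else NULL
    callPos <- if (!is.null(tssCalls)) start(tssCalls) else integer(0)

    tuList <- split(seq_len(n), tuIdx)
    rngStart <- integer(length(tuList)); rngEnd <- integer(length(tuList))
    geneIds <- vector("list", length(tuList))
    tssIds <- vector("list", length(tuList))
    attens <- vector("list", length(tuList))
    terminal <- rep(NA_character_, length(tuList))
    spans <- integer(length(tuList))
    strs <- character(length(tuList))
    for (k in seq_along(tuList)) {
        gi <- tuList[[k]]
        strs[k] <- gStr[gi[1L]]
        rngStart[k] <- min(gStart[gi]); rngEnd[k] <- max(gEnd[gi])
        geneIds[[k]] <- ids[gi]
        inner <- gi[-length(gi)]
        att <- unlist(attenAfter[inner], use.names = FALSE)
        attens[[k]] <- if (is.null(att)) character(0) else att
        sel <- if (!is.null(callGene)) which(callGene %in% ids[gi])
               else integer(0)
        tssIds[[k]] <- if (length(sel)) callId[sel] else character(0)
        lo <- rngStart[k]; hi <- rngEnd[k]
        if (length(sel)) {
            lo <- min(lo, callPos[sel]); hi <- max(hi, callPos[sel])
        }
        spans[k] <- hi - lo + 1L
        dn <- if (strs[k] == "+")
            term$strand == "+" & term$position > rngEnd[k] &
                term$position <= rngEnd[k] + maxGap
        else
            term$strand == "-" & term$position < rngStart[k] &
                term$position >= rngStart[k] - maxGap
        dn <- dn & !(term$term_id %in% attens[[k]])
        if (any(dn)) {
            cand <- which(dn)
            terminal[k] <- term$term_id[cand[which.min(term$delta_g[cand])]]
        }
    }
    gr <- GRanges("chr", IRanges(rngStart, rngEnd), strand = strs)
    mcols(gr)$tu_id <- sprintf("TU_%02d", seq_along(tuList))
    mcols(gr)$gene_ids <- CharacterList(geneIds)
    mcols(gr)$n_genes <- lengths(geneIds)
    mcols(gr)$tss_ids <- CharacterList(tssIds)
    mcols(gr)$terminator <- terminal
    mcols(gr)$attenuators <- CharacterList(attens)
    mcols(gr)$span <- spans
    gr
}

#' Report the TSS architecture of precursor-peptide genes
#'
#' For each designated precursor gene: whether it has a dedicated TSS
#' (a call assigned to it), whether that TSS is intragenic (lying inside
#' the span of another gene, i.e. its call is classified `internal`), the
#' 5'UTR length, and the gene's position in its transcription unit (first
#' gene in transcription order vs internal). This is the genome-wide
#' screen for the pattern in which a precursor gene buried in an operon
#' still carries its own start, often overlapping the end of the
#' preceding gene.
#'
#' @param genes annotation [GenomicRanges::GRanges] with `gene_id`.
#' @param tssCalls classified calls from [classifyTss()].
#' @param precursorIds character vector of precursor gene ids; unknown ids
#'   error.
#' @param tus optional transcription units from
#'   [inferTranscriptionUnits()]; without them `tu_id`/`tu_position` are
#'   `NA`.
#' @return A data.frame with one row per precursor: `precursor_id`,
#'   `dedicated_tss`, `intragenic`, `tss_position`, `utr_length`,
#'   `tu_id`, `tu_position`.
#' @export
precursorTssReport <- function(genes, tssCalls, precursorIds, tus = NULL) {
    ids <- mcols(genes)$gene_id
    unknown <- setdiff(precursorIds, ids)
    if (length(unknown))
        stop("unknown precursor id(s): ", paste(unknown, collapse = ", "))
    callGene <- mcols(tssCalls)$gene
    rows <- lapply(precursorIds, function(pid) {
        sel <- which(!is.na(callGene) & callGene == pid)
        dedicated <- length(sel) > 0L
        if (dedicated && length(sel) > 1L)
            sel <- sel[which.max(mcols(tssCalls)$score[sel])]
        tuId <- NA_character_; tuPos <- NA_character_
        if (!is.null(tus)) {
            k <- which(vapply(mcols(tus)$gene_ids,
                              function(g) pid %in% g, logical(1)))
            if (length(k) == 1L) {
                tuId <- mcols(tus)$tu_id[k]
                g <- mcols(tus)$gene_ids[[k]]
                first <- if (as.character(strand(tus))[k] == "+")
                    g[1L] else g[length(g)]
                tuPos <- if (identical(first, pid)) "first" else "internal"
            }
        }
        data.frame(precursor_id = pid,
                   dedicated_tss = dedicated,
                   intragenic = if (dedicated)
                       mcols(tssCalls)$category[sel] == "internal" else NA,
                   tss_position = if (dedicated) start(tssCalls)[sel]
                                  else NA_integer_,
                   utr_length = if (dedicated)
                       mcols(tssCalls)$utr_length[sel] else NA_integer_,
                   tu_id = tuId,
                   tu_position = tuPos,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Filter DNA-affinity-capture protein hits for candidate regulators
#'
#' Partitions the identified proteins into those shared by both growth
#' conditions, those exclusive to the production condition and those
#' exclusive to the control condition; candidate regulators are the
#' production-only hits annotated as regulators or uncharacterized
#' proteins. Input order is preserved within blocks.
#'
#' @param hits data.frame with columns `protein_id` (unique),
#'   `in_production`, `in_control` (logical; at least one `TRUE` per row)
#'   and `annotation_class` (`"regulator"`, `"uncharacterized"` or
#'   `"other"`).
#' @return A list: `sizes` (named integer vector `shared`,
#'   `production_only`, `control_only`), `partition` (the input with a
#'   `block` column) and `candidates` (the filtered data.frame).
#' @seealso [dacaFixture()]
#' @export
dacaCandidateFilter <- function(hits) {
    if (NROW(hits) == 0L)
        return(list(sizes = c(shared = 0L, production_only = 0L,
                              control_only = 0L),
                    partition = cbind(hits,
                                      block = character(0)),
                    candidates = hits))
    if (anyDuplicated(hits$protein_id))
        stop("duplicate protein id(s): ",
             paste(unique(hits$protein_id[duplicated(hits$protein_id)]),
                   collapse = ", "))
    if (any(!hits$in_production & !hits$in_control))
        stop("every hit must be present in at least one condition")
    block <- ifelse(hits$in_production & hits$in_control, "shared",
                    ifelse(hits$in_production, "production_only",
                           "control_only"))
    sizes <- c(shared = sum(block == "shared"),
               production_only = sum(block == "production_only"),
               control_only = sum(block == "control_only"))
    partition <- hits
    partition$block <- block
    candidates <- hits[block == "production_only" &
                       hits$annotation_class %in%
                           c("regulator", "uncharacterized"), ,
                       drop = FALSE]
    list(sizes = sizes, partition = partition, candidates = candidates)
}

#' Build a synthetic DNA-affinity-capture hit table
#'
#' Generates a protein-hit table with the requested condition-partition
#' block sizes and seed-deterministic annotation classes, for exercising
#' [dacaCandidateFilter()]. The defaults mirror the published partition of
#' the capture experiment (120 shared, 177 production-only, 24
#' control-only identifications); annotation classes are drawn at random
#' and make no claim about the real annotations.
#'
#' @param nShared,nProductionOnly,nControlOnly block sizes.
#' @param classProbs sampling probabilities for annotation classes
#'   regulator / uncharacterized / other.
#' @param seed RNG seed.
#' @return A data.frame suitable for [dacaCandidateFilter()].
#' @export
dacaFixture <- function(nShared = 120L, nProductionOnly = 177L,
                        nControlOnly = 24L,
                        classProbs = c(0.02, 0.10, 0.88), seed = 1L) {
    set.seed(seed)
    n <- nShared + nProductionOnly + nControlOnly
    data.frame(
        protein_id = sprintf("P%04d", seq_len(n)),
        in_production = rep(c(TRUE, TRUE, FALSE),
                            c(nShared, nProductionOnly, nControlOnly)),
        in_control = rep(c(TRUE, FALSE, TRUE),
                         c(nShared, nProductionOnly, nControlOnly)),
        annotation_class = sample(c("regulator", "uncharacterized", "other"),
                                  n, replace = TRUE, prob = classProbs),
        stringsAsFactors = FALSE)
}
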