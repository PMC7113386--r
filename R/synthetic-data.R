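## Ground-truthed tagRNA-seq simulator. Generates a genome with a
## bottromycin-like gene cluster (two divergent minus-strand genes, then a
## tightly packed plus-strand run whose precursor gene carries a dedicated
## TSS inside the preceding gene), planted TSS/processing-site truth,
## transcript models with attenuators, and tagged read sets.

.randomDna <- function(length, gcFraction) {
    p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
           G = gcFraction / 2, T = (1 - gcFraction) / 2)
    DNAString(paste(sample(names(p), length, replace = TRUE, prob = p),
                    collapse = ""))
}

## Remove every exact occurrence of the tag sequences (either strand)
## from the genome by mutating one base, so that no untagged read can
## mimic a tagged one and demultiplexing is exactly invertible on
## simulated data.
.scrubTags <- function(dna, tags = c("TAATGCGC", "CTGAAGCT")) {
    pats <- unique(c(tags, vapply(tags, function(t)
        as.character(reverseComplement(DNAString(t))), character(1))))
    for (iter in 1:10) {
        hit <- FALSE
        for (pat in pats) {
            m <- Biostrings::matchPattern(pat, dna)
            if (length(m) == 0L) next
            hit <- TRUE
            for (s in IRanges::start(m)) {
                p <- s + 4L
                cur <- as.character(subseq(dna, p, p))
                subseq(dna, p, p) <- DNAString(
                    sample(setdiff(c("A", "C", "G", "T"), cur), 1L))
            }
        }
        if (!hit) break
    }
    dna
}

## Fixed geometry of the 13-gene cluster. Coordinates are chosen so that
## the precursor gene's dedicated TSS sits 348 nt upstream of its start
## codon and 215 nt before the end of the preceding gene, the two
## upstream genes are divergent from the run, intergenic gaps inside the
## run stay under 300 nt, and all same-strand planted sites are >= 50 nt
## apart.
.btmClusterLayout <- function() {
    ids <- paste0("gene_", LETTERS[1:13])
    starts <- c(5000, 6100, 7100, 8482, 8900, 10018, 10978, 12118, 12953,
                13973, 14698, 15943, 16648)
    ends <- c(5899, 6899, 8349, 8781, 9899, 10917, 12077, 12917, 13902,
              14672, 15897, 16592, 17647)
    strands <- c("-", "-", rep("+", 11))
    genes <- data.frame(gene_id = ids, start = starts, end = ends,
                        strand = strands, stringsAsFactors = FALSE)
    sites <- data.frame(
        site_id = c("TSS_gene_A", "TSS_gene_B", "TSS_gene_C", "TSS_gene_D",
                    "PS_01", "PS_02", "PS_03", "PS_04"),
        kind = c(rep("TSS", 4), rep("PS", 4)),
        position = c(5939, 6969, 7068, 8134, 7500, 9100, 12500, 6500),
        strand = c("-", "-", "+", "+", "+", "+", "+", "-"),
        strength = c(60, 80, 150, 200, 120, 90, 60, 70),
        gene_id = c("gene_A", "gene_B", "gene_C", "gene_D",
                    NA, NA, NA, NA),
        stringsAsFactors = FALSE)
    transcripts <- data.frame(
        transcript_id = c("t_A", "t_B", "t_C", "t_D"),
        site_id = c("TSS_gene_A", "TSS_gene_B", "TSS_gene_C", "TSS_gene_D"),
        tss_position = c(5939, 6969, 7068, 8134),
        strand = c("-", "-", "+", "+"),
        end_position = c(4980, 6080, 17667, 17667),
        stringsAsFactors = FALSE)
    transcripts$attenuators <- list(integer(0), integer(0), 8840L, 8840L)
    transcripts$readthrough <- list(numeric(0), numeric(0), 0.3, 0.3)
    terminators <- data.frame(
        term_id = c("term_A", "term_AB", "atten_DE", "term_M"),
        position = c(4950, 6000, 8840, 17707),
        strand = c("-", "-", "+", "+"),
        delta_g = c(-19.5, -19.43, -12.0, -19.0),
        stringsAsFactors = FALSE)
    list(genes = genes, sites = sites, transcripts = transcripts,
         terminators = terminators, promoter35 = c(7032, 7037),
         promoter10 = c(7055, 7060), clusterEnd = 17807)
}

.backgroundLayout <- function(nBg, origin = 18500L, step = 2400L,
                              geneLen = 1000L) {
    if (nBg == 0L)
        return(list(genes = NULL, sites = NULL, transcripts = NULL,
                    lastEnd = 0L))
    s <- origin + (seq_len(nBg) - 1L) * step
    e <- s + geneLen - 1L
    str <- rep(c("+", "-"), length.out = nBg)
    ids <- sprintf("bg_%02d", seq_len(nBg))
    tssPos <- ifelse(str == "+", s - 50L, e + 50L)
    strengths <- round(seq(20, 200, length.out = nBg))
    genes <- data.frame(gene_id = ids, start = s, end = e, strand = str,
                        stringsAsFactors = FALSE)
    sites <- data.frame(site_id = paste0("TSS_", ids), kind = "TSS",
                        position = tssPos, strand = str,
                        strength = strengths, gene_id = ids,
                        stringsAsFactors = FALSE)
    psIdx <- which(seq_len(nBg) %% 3L == 0L)
    if (length(psIdx)) {
        ps <- data.frame(site_id = sprintf("PS_bg_%02d", psIdx),
                         kind = "PS", position = s[psIdx] + 400L,
                         strand = str[psIdx], strength = 80,
                         gene_id = NA_character_,
                         stringsAsFactors = FALSE)
        sites <- rbind(sites, ps)
    }
    transcripts <- data.frame(
        transcript_id = paste0("t_", ids),
        site_id = paste0("TSS_", ids),
        tss_position = tssPos,
        strand = str,
        end_position = ifelse(str == "+", e + 20L, s - 20L),
        stringsAsFactors = FALSE)
    transcripts$attenuators <- rep(list(integer(0)), nBg)
    transcripts$readthrough <- rep(list(numeric(0)), nBg)
    list(genes = genes, sites = sites, transcripts = transcripts,
         lastEnd = max(e) + 100L)
}

#' Generate a synthetic genome with planted TSS/processing-site truth
#'
#' Builds a random high-GC genome (a stand-in for a *Streptomyces*-like
#' chromosome), a gene annotation, planted transcription start sites and
#' processing sites with expected read strengths, transcript models (with
#' a read-through attenuator inside the cluster operon) and intrinsic
#' terminator records. Two layouts are available:
#'
#' * `"btm-like"`: a 13-gene cluster - two divergent genes on the minus
#'   strand, then an 11-gene plus-strand run. The run's second gene is the
#'   designated precursor-peptide gene; its dedicated TSS is planted 348 nt
#'   upstream of its start codon, inside the preceding gene (215 nt before
#'   that gene's end). A consensus -35/-10 promoter is planted upstream of
#'   the run's first TSS. Genes beyond the 13th become background genes,
#'   each with its own TSS (strengths spanning 20-200) and interleaved
#'   processing sites.
#' * `"uniform"`: `nGenes` equal-length plus-strand genes with one TSS
#'   each and random strengths.
#'
#' Same-strand planted sites are always at least `minSiteSeparation` nt
#' apart, making recovery unambiguous. Output is deterministic for a fixed
#' seed.
#'
#' @param length genome length in nt (>= 1000).
#' @param gcFraction GC content of the random background sequence.
#' @param nGenes total number of genes (>= 13 for `"btm-like"`).
#' @param layout `"btm-like"` or `"uniform"`.
#' @param seed RNG seed.
#' @param minSiteSeparation enforced minimum same-strand site separation.
#' @return A list: `genome` ([Biostrings::DNAStringSet], one sequence
#'   named `chr`), `genes` ([GenomicRanges::GRanges] with `gene_id`,
#'   `role`, `precursor`), `sites` (data.frame of planted truth: site_id,
#'   kind TSS/PS, position, strand, strength, gene_id), `transcripts`
#'   (data.frame with list-columns `attenuators`, `readthrough`),
#'   `terminators` (data.frame), `precursorId`, `layout`, `seed`.
#' @examples
#' fx <- generateGenome(length = 20000, nGenes = 13, seed = 1)
#' table(as.character(GenomicRanges::strand(fx$genes)))
#' @export
generateGenome <- function(length = 100000L, gcFraction = 0.71,
                           nGenes = 13L, layout = c("btm-like", "uniform"),
                           seed = 1L, minSiteSeparation = 50L) {
    layout <- match.arg(layout)
    length <- as.integer(length)
    nGenes <- as.integer(nGenes)
    if (nGenes < 1L) stop("nGenes must be at least 1")
    if (length < 1000L) stop("genome length must be at least 1000 nt")
    set.seed(seed)
    if (layout == "btm-like") {
        if (nGenes < 13L)
            stop("btm-like layout needs at least 13 genes")
        cl <- .btmClusterLayout()
        bg <- .backgroundLayout(nGenes - 13L)
        required <- max(cl$clusterEnd, bg$lastEnd)
        if (length < required)
            stop(sprintf(
                "genome length %d too short for layout: need at least %d (deficit %d nt)",
                length, required, required - length))
        genesDf <- rbind(cbind(cl$genes, role = "cluster"),
                         if (!is.null(bg$genes))
                             cbind(bg$genes, role = "background"))
        sites <- rbind(cl$sites, bg$sites)
        transcripts <- rbind(cl$transcripts, bg$transcripts)
        terminators <- cl$terminators
        precursorId <- "gene_D"
        seqDna <- .randomDna(length, gcFraction)
        subseq(seqDna, cl$promoter35[1], cl$promoter35[2]) <- DNAString("TTGACA")
        subseq(seqDna, cl$promoter10[1], cl$promoter10[2]) <- DNAString("TATAAT")
        seqDna <- .scrubTags(seqDna)
    } else {
        s <- 2000L + (seq_len(nGenes) - 1L) * 2400L
        e <- s + 999L
        required <- max(e) + 100L
        if (length < required)
            stop(sprintf(
                "genome length %d too short for layout: need at least %d (deficit %d nt)",
                length, required, required - length))
        ids <- sprintf("gene_%02d", seq_len(nGenes))
        genesDf <- data.frame(gene_id = ids, start = s, end = e,
                              strand = "+", role = "uniform",
                              stringsAsFactors = FALSE)
        sites <- data.frame(site_id = paste0("TSS_", ids), kind = "TSS",
                            position = s - 50L, strand = "+",
                            strength = round(runif(nGenes, 20, 200)),
                            gene_id = ids, stringsAsFactors = FALSE)
        transcripts <- data.frame(
            transcript_id = paste0("t_", ids), site_id = paste0("TSS_", ids),
            tss_position = s - 50L, strand = "+", end_position = e + 20L,
            stringsAsFactors = FALSE)
        transcripts$attenuators <- rep(list(integer(0)), nGenes)
        transcripts$readthrough <- rep(list(numeric(0)), nGenes)
        terminators <- data.frame(term_id = character(0),
                                  position = integer(0),
                                  strand = character(0),
                                  delta_g = numeric(0),
                                  stringsAsFactors = FALSE)
        precursorId <- NA_character_
        seqDna <- .scrubTags(.randomDna(length, gcFraction))
    }
    ## enforce the separation invariant on the planted truth
    for (st in c("+", "-")) {
        p <- sort(sites$position[sites$strand == st])
        if (length(p) > 1L && min(diff(p)) < minSiteSeparation)
            stop("internal error: planted sites closer than minSiteSeparation")
    }
    genome <- DNAStringSet(seqDna)
    names(genome) <- "chr"
    genes <- GRanges("chr", IRanges(genesDf$start, genesDf$end),
                     strand = genesDf$strand)
    seqlengths(genes) <- c(chr = length)
    mcols(genes)$gene_id <- genesDf$gene_id
    mcols(genes)$role <- genesDf$role
    mcols(genes)$precursor <- genesDf$gene_id == precursorId &
        !is.na(precursorId)
    rownames(sites) <- NULL
    rownames(transcripts) <- NULL
    list(genome = genome, genes = genes, sites = sites,
         transcripts = transcripts, terminators = terminators,
         precursorId = precursorId, layout = layout, seed = seed)
}

## Segment table for internal-fragment sampling: one row per
## (transcript, inter-attenuator segment), with the eligible window of
## 5'-start positions and the sampling weight (strength x read-through
## factor x window length).
.fragmentSegments <- function(transcripts, sites, readLength) {
    strength <- sites$strength[match(transcripts$site_id, sites$site_id)]
    rows <- list()
    for (i in seq_len(nrow(transcripts))) {
        tss <- transcripts$tss_position[i]
        endp <- transcripts$end_position[i]
        str <- transcripts$strand[i]
        att <- transcripts$attenuators[[i]]
        rt <- transcripts$readthrough[[i]]
        tlen <- abs(endp - tss) + 1L
        if (tlen < readLength)
            stop(sprintf(
                "read length %d longer than transcript %s (%d nt)",
                readLength, transcripts$transcript_id[i], tlen))
        if (str == "+") {
            bounds <- c(tss, sort(att), endp)
            factors <- cumprod(c(1, rt[order(att)]))
            for (k in seq_len(length(bounds) - 1L)) {
                lo <- if (k == 1L) bounds[1L] else bounds[k] + 1L
                hi <- min(bounds[k + 1L], endp - readLength + 1L)
                if (hi < lo) next
                rows[[length(rows) + 1L]] <- data.frame(
                    strand = str, lo = lo, hi = hi,
                    w = strength[i] * factors[k] * (hi - lo + 1L))
            }
        } else {
            bounds <- c(tss, sort(att, decreasing = TRUE), endp)
            factors <- cumprod(c(1, rt[order(att, decreasing = TRUE)]))
            for (k in seq_len(length(bounds) - 1L)) {
                hi <- if (k == 1L) bounds[1L] else bounds[k] - 1L
                lo <- max(bounds[k + 1L], endp + readLength - 1L)
                if (hi < lo) next
                rows[[length(rows) + 1L]] <- data.frame(
                    strand = str, lo = lo, hi = hi,
                    w = strength[i] * factors[k] * (hi - lo + 1L))
            }
        }
    }
    do.call(rbind, rows)
}

.substitute <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    chars <- c("A", "C", "G", "T")
    for (i in seq_along(seqs)) {
        s <- seqs[i]
        hit <- which(runif(nchar(s)) < rate)
        if (!length(hit)) next
        v <- strsplit(s, "")[[1]]
        for (p in hit) v[p] <- sample(setdiff(chars, v[p]), 1L)
        seqs[i] <- paste(v, collapse = "")
    }
    seqs
}

#' Simulate a tagged tagRNA-seq read set with full ground truth
#'
#' Emits three read species, mirroring the library chemistry:
#'
#' * primary-tagged reads - the primary tag followed by genome sequence
#'   starting exactly at a planted TSS (reverse-complemented for minus
#'   strand sites, tag still at the read's 5' end, so demultiplexing is
#'   orientation-free);
#' * processed-tagged reads - the processed tag followed by sequence
#'   starting at a planted processing site;
#' * untagged internal fragments starting uniformly within a transcript
#'   body, with density reduced downstream of each attenuator by its
#'   read-through fraction.
#'
#' Per-site read counts are Poisson draws around the site strength. When
#' `nReads` is given, strengths are first rescaled so that tagged reads
#' make up `1 - internalFragmentFraction` of the library and exactly
#' `nReads` reads are emitted; with `nReads = NULL` the strengths are used
#' as expected counts directly and the library size emerges. Each 5' end
#' receives its correct tag with probability `tagEfficiency`, the wrong
#' tag with probability `mistagRate`, and no tag otherwise. Optional
#' uniform substitutions are applied to the transcript-derived portion of
#' each read (never the tag).
#'
#' @param genome [Biostrings::DNAStringSet] from [generateGenome()].
#' @param sites planted-site data.frame (`$sites` of the fixture).
#' @param transcripts transcript models (`$transcripts` of the fixture).
#' @param readLength sequenced read length after the tag (default 75 nt).
#' @param nReads total library size, or `NULL` (see above).
#' @param tagEfficiency probability a 5' end receives its correct tag.
#' @param mistagRate probability it receives the wrong tag;
#'   `tagEfficiency + mistagRate` must not exceed 1.
#' @param internalFragmentFraction expected fraction of untagged internal
#'   fragments in the library. The tagRNA-seq protocol keeps full
#'   transcriptome coverage, so a substantial untagged fraction is
#'   realistic; the default 0.5 is a free parameter, not an estimate.
#' @param substitutionRate per-base substitution probability (default 0).
#' @param tags a [TagSpec-class] providing the tag sequences.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A list: `reads` ([ShortRead::ShortReadQ]: tagged reads are
#'   `readLength + tag` long, untagged `readLength`; constant Q40
#'   qualities), `sam` (data.frame of error-free alignments of the
#'   trimmed reads: FLAG 0/16, leftmost POS, `<readLength>M` CIGAR),
#'   `truth` (data.frame mapping read id to tag class, origin TSS /
#'   PS / internal, site id, 5' genomic position and strand),
#'   `genomeLength`, `readLength`.
#' @seealso [writeSimulatedReads()]
#' @export
simulateTaggedReads <- function(genome, sites, transcripts,
                                readLength = 75L, nReads = 200000L,
                                tagEfficiency = 0.9, mistagRate = 0.01,
                                internalFragmentFraction = 0.5,
                                substitutionRate = 0, tags = tagSpec(),
                                seed = 1L) {
    stopifnot(tagEfficiency >= 0, tagEfficiency <= 1,
              mistagRate >= 0, mistagRate <= 1,
              internalFragmentFraction >= 0, internalFragmentFraction <= 1)
    if (tagEfficiency + mistagRate > 1)
        stop("tagEfficiency + mistagRate must not exceed 1")
    readLength <- as.integer(readLength)
    L <- width(genome)[1L]
    if (any(sites$position < 1L | sites$position > L))
        stop("planted site outside genome")
    set.seed(seed)

    iff <- internalFragmentFraction
    lam <- if (!is.null(nReads)) {
        sites$strength * (nReads * (1 - iff)) / sum(sites$strength)
    } else sites$strength
    siteCounts <- rpois(nrow(sites), lam)
    siteIdx <- rep(seq_len(nrow(sites)), siteCounts)
    if (!is.null(nReads) && length(siteIdx) > nReads)
        siteIdx <- sort(sample(siteIdx, nReads))
    nSite <- length(siteIdx)
    nInternal <- if (!is.null(nReads)) nReads - nSite
        else if (iff >= 1) stop("internalFragmentFraction = 1 requires nReads")
        else round(nSite * iff / (1 - iff))
    if (nInternal > 0L && iff == 0) {
        ## no internal fragments requested: top the library up to nReads
        ## with extra site reads drawn proportionally to strength
        extra <- sample(nrow(sites), nInternal, replace = TRUE,
                        prob = sites$strength)
        siteIdx <- c(siteIdx, extra)
        nSite <- length(siteIdx)
        nInternal <- 0L
    }

    ## tag assignment for site reads
    u <- runif(nSite)
    correct <- u < tagEfficiency
    wrong <- !correct & u < tagEfficiency + mistagRate
    kind <- sites$kind[siteIdx]
    tagClass <- rep("untagged", nSite)
    tagClass[correct] <- ifelse(kind[correct] == "TSS", "primary",
                                "processed")
    tagClass[wrong] <- ifelse(kind[wrong] == "TSS", "processed", "primary")
    sitePos <- sites$position[siteIdx]
    siteStr <- sites$strand[siteIdx]

    ## internal fragments
    if (nInternal > 0L) {
        if (is.null(transcripts) || nrow(transcripts) == 0L)
            stop("internal fragments requested but no transcripts given")
        seg <- .fragmentSegments(transcripts, sites, readLength)
        pick <- sample(nrow(seg), nInternal, replace = TRUE, prob = seg$w)
        intPos <- seg$lo[pick] +
            floor(runif(nInternal) * (seg$hi[pick] - seg$lo[pick] + 1L))
        intStr <- seg$strand[pick]
    } else {
        ## still validates transcript lengths against the read length
        if (!is.null(transcripts) && nrow(transcripts) > 0L)
            .fragmentSegments(transcripts, sites, readLength)
        intPos <- integer(0)
        intStr <- character(0)
    }

    pos5 <- c(sitePos, intPos)
    str <- c(siteStr, intStr)
    tagClass <- c(tagClass, rep("untagged", nInternal))
    origin <- c(kind, rep("internal", nInternal))
    siteId <- c(sites$site_id[siteIdx], rep(NA_character_, nInternal))
    n <- length(pos5)
    ids <- sprintf("read_%06d", seq_len(n))

    lft <- ifelse(str == "+", pos5, pos5 - readLength + 1L)
    rgt <- ifelse(str == "+", pos5 + readLength - 1L, pos5)
    if (any(lft < 1L | rgt > L))
        stop("simulated read extends outside the genome; enlarge the margins")
    fwd <- as.character(extractAt(genome[[1L]], IRanges(lft, rgt)))
    fwd <- .substitute(fwd, substitutionRate)
    readSeq <- fwd
    minus <- str == "-"
    if (any(minus))
        readSeq[minus] <- as.character(
            reverseComplement(DNAStringSet(fwd[minus])))
    tagSeq <- c(primary = tags@primary, processed = tags@processed,
                untagged = "")[tagClass]
    fullSeq <- paste0(tagSeq, readSeq)

    qual <- strrep("I", nchar(fullSeq))
    reads <- ShortReadQ(sread = DNAStringSet(fullSeq),
                        quality = FastqQuality(Biostrings::BStringSet(qual)),
                        id = Biostrings::BStringSet(ids))
    sam <- data.frame(qname = ids,
                      flag = ifelse(minus, 16L, 0L),
                      rname = "chr",
                      pos = as.integer(lft),
                      mapq = 42L,
                      cigar = paste0(readLength, "M"),
                      seq = fwd,
                      stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids,
                        tag_class = tagClass,
                        origin = origin,
                        site_id = siteId,
                        position = as.integer(pos5),
                        strand = str,
                        stringsAsFactors = FALSE)
    list(reads = reads, sam = sam, truth = truth,
         genomeLength = L, readLength = readLength)
}

#' Write a simulated read set to FASTQ, SAM and truth-table files
#'
#' @param sim result of [simulateTaggedReads()].
#' @param prefix output path prefix; writes `<prefix>.fastq`,
#'   `<prefix>.sam` (with `@SQ` header; the error-free truth alignment of
#'   each trimmed read) and `<prefix>.truth.tsv`.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSimulatedReads <- function(sim, prefix) {
    fq <- paste0(prefix, ".fastq")
    samPath <- paste0(prefix, ".sam")
    truthPath <- paste0(prefix, ".truth.tsv")
    writeFastq(sim$reads, fq, mode = "w", compress = FALSE)
    qual <- strrep("I", nchar(sim$sam$seq))
    lines <- c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:chr\tLN:%d", sim$genomeLength),
               paste(sim$sam$qname, sim$sam$flag, sim$sam$rname,
                     sim$sam$pos, sim$sam$mapq, sim$sam$cigar,
                     "*", 0L, 0L, sim$sam$seq, qual, sep = "\t"))
    writeLines(lines, samPath)
    write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(fastq = fq, sam = samPath, truth = truthPath))
}
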