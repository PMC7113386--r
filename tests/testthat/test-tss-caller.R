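trk <- function(plus, minus = NULL, class = "primary", sample = "s1") {
    if (is.null(minus)) minus <- numeric(length(plus))
    startTrack(plus, minus, class, sample)
}

test_that("quantile normalization equalizes depth between samples", {
    out <- quantileNormalizeTracks(list(trk(c(1, 2, 3)), trk(c(4, 5, 6),
                                        sample = "s2")))
    expect_equal(trackValues(out[[1]], "+"), c(2.5, 3.5, 4.5))
    expect_equal(trackValues(out[[2]], "+"), c(2.5, 3.5, 4.5))
    # identical tracks are a fixed point; a single track passes through
    two <- quantileNormalizeTracks(list(trk(c(7, 0, 2)), trk(c(7, 0, 2),
                                        sample = "s2")))
    expect_equal(trackValues(two[[1]], "+"), c(7, 0, 2))
    one <- quantileNormalizeTracks(list(trk(c(9, 1, 4))))
    expect_equal(trackValues(one[[1]], "+"), c(9, 1, 4))
    expect_error(quantileNormalizeTracks(list(trk(1:3), trk(1:4,
                                              sample = "s2"))),
                 "equal genome length")
})

test_that("tied positions receive the mean over their rank block", {
    # second sample has three tied 1s spanning sort ranks 1..3: they all
    # get mean(rank means 0.5, 0.5, 1.5) = 5/6... computed by the oracle
    M <- cbind(c(0, 0, 5, 2), c(1, 1, 1, 9))
    out <- quantileNormalizeTracks(list(trk(M[, 1]), trk(M[, 2],
                                        sample = "s2")))
    want <- oracleQuantileNormalize(M)
    expect_equal(trackValues(out[[1]], "+"), want[, 1])
    expect_equal(trackValues(out[[2]], "+"), want[, 2])
    expect_equal(trackValues(out[[2]], "+")[1], 2.5 / 3)
})

test_that("normalization agrees with the oracle and with limma on ties-free data", {
    set.seed(31)
    for (rep in 1:8) {
        n <- sample(10:40, 1)
        k <- sample(2:4, 1)
        M <- matrix(runif(n * k) * 100, n, k)  # continuous: no ties
        tracks <- lapply(seq_len(k), function(j)
            trk(M[, j], sample = paste0("s", j)))
        out <- quantileNormalizeTracks(tracks)
        got <- sapply(out, trackValues, strand = "+")
        expect_equal(got, oracleQuantileNormalize(M))
        expect_equal(unname(got), unname(limma::normalizeQuantiles(M)))
        # all samples share one sorted value vector afterwards
        sorted <- apply(got, 2, sort)
        for (j in seq_len(k)) expect_equal(sorted[, j], sorted[, 1])
    }
})

test_that("track subtraction is positionwise with optional clamping", {
    net <- subtractTracks(trk(c(5, 0, 10)), trk(c(2, 3, 4),
                          class = "processed"))
    expect_equal(trackValues(net, "+"), c(3, 0, 6))
    expect_equal(trackClass(net), "net")
    raw <- subtractTracks(trk(c(5, 0, 10)), trk(c(2, 3, 4),
                          class = "processed"), clamp = FALSE)
    expect_equal(trackValues(raw, "+"), c(3, -3, 6))
    # processed all zero leaves primary; equal tracks vanish
    expect_equal(trackValues(subtractTracks(trk(c(1, 2)), trk(c(0, 0),
                             class = "processed")), "+"), c(1, 2))
    expect_equal(trackValues(subtractTracks(trk(c(4, 4)), trk(c(4, 4),
                             class = "processed")), "+"), c(0, 0))
    expect_error(subtractTracks(trk(1:3), trk(1:4, class = "processed")),
                 "length mismatch")
    expect_error(subtractTracks(trk(1:3), trk(1:3, class = "processed",
                                              sample = "other")),
                 "different samples")
    set.seed(32)
    for (rep in 1:10) {
        p <- rpois(50, 3); q <- rpois(50, 3)
        net <- subtractTracks(trk(p), trk(q, class = "processed"))
        expect_equal(trackValues(net, "+"), oracleSubtract(p, q))
        expect_true(all(trackValues(net, "+") >= 0))
    }
})

test_that("TSS calling thresholds and merges candidate positions", {
    v <- numeric(1000); v[500] <- 50
    calls <- callTss(trk(v, class = "net"), minCount = 10)
    expect_equal(start(calls), 500L)
    expect_equal(mcols(calls)$score, 50)
    # neighbours within the merge window collapse to the signal maximum
    v2 <- numeric(1000); v2[499:501] <- c(20, 50, 10)
    calls2 <- callTss(trk(v2, class = "net"), minCount = 10,
                      mergeWindow = 3)
    expect_equal(start(calls2), 500L)
    expect_equal(mcols(calls2)$score, 50)
    # a tie resolves to the smallest coordinate
    v3 <- numeric(1000); v3[700:701] <- c(30, 30)
    expect_equal(start(callTss(trk(v3, class = "net"))), 700L)
    # sub-threshold signal yields no calls
    v4 <- numeric(1000); v4[100] <- 5
    expect_equal(length(callTss(trk(v4, class = "net"), minCount = 10)), 0L)
    expect_error(callTss(trk(v, class = "net"), minCount = 0),
                 "positive")
})

test_that("TSS classification assigns genes, categories and 5'UTRs", {
    genes <- mkGenes(c(1, 1201), c(1000, 1800), "+", c("gC", "gD"))
    mk <- function(pos, str = "+") {
        gr <- GRanges("chr", IRanges(pos, width = 1), strand = str)
        mcols(gr)$tss_id <- "tss_0001"; mcols(gr)$score <- 50
        gr
    }
    # intragenic call upstream of gD inside gC
    c1 <- classifyTss(mk(900), genes)
    expect_equal(mcols(c1)$gene, "gD")
    expect_equal(as.character(mcols(c1)$category), "internal")
    expect_equal(mcols(c1)$utr_length, 301L)
    expect_equal(as.character(mcols(c1)$leadered_class),
                 "extended_leadered")
    # leaderless gene TSS just upstream of gD
    c2 <- classifyTss(mk(1195), genes)
    expect_equal(mcols(c2)$gene, "gD")
    expect_equal(as.character(mcols(c2)$category), "gene_tss")
    expect_equal(mcols(c2)$utr_length, 6L)
    expect_equal(as.character(mcols(c2)$leadered_class), "leaderless")
    # antisense: opposite strand inside a gene, no same-strand target
    c3 <- classifyTss(mk(500, "-"), genes)
    expect_equal(as.character(mcols(c3)$category), "antisense")
    expect_true(is.na(mcols(c3)$gene))
    # orphan: nothing downstream within range, not inside any gene
    c4 <- classifyTss(mk(5000), genes)
    expect_equal(as.character(mcols(c4)$category), "orphan")
    # minus-strand UTR arithmetic mirrors the plus strand
    genesM <- mkGenes(2000, 2600, "-", "gM")
    c5 <- classifyTss(mk(2630, "-"), genesM)
    expect_equal(mcols(c5)$gene, "gM")
    expect_equal(mcols(c5)$utr_length, 30L)
})

test_that("promoter scanning recovers planted consensus boxes", {
    set.seed(33)
    base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    up <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    # plant TTGACA ... 17 nt ... TATAAT ... 7 nt ... TSS
    substr(up, 48 - 17 - 6, 48 - 17 - 1) <- "TTGACA"
    substr(up, 48, 53) <- "TATAAT"
    genome <- DNAStringSet(paste0(base, up, base))
    names(genome) <- "chr"
    hit <- promoterBoxScan(genome, 461, "+")
    expect_equal(hit$mismatches, 0)
    expect_equal(hit$spacer, 17)
    expect_equal(hit$minus35, "TTGACA")
    expect_equal(hit$minus10, "TATAAT")
    # poly-C upstream has no acceptable placement at a tight threshold
    polyC <- DNAStringSet(paste(rep("C", 200), collapse = ""))
    names(polyC) <- "chr"
    expect_null(suppressWarnings(
        promoterBoxScan(polyC, 150, "+", maxMismatches = 4)))
    # too little upstream context warns and returns nothing
    expect_warning(res <- promoterBoxScan(genome, 30, "+"), "insufficient")
    expect_null(res)
})

test_that("promoter scan scores equal the exhaustive minimum", {
    set.seed(34)
    for (rep in 1:12) {
        seqchr <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                        collapse = "")
        genome <- DNAStringSet(seqchr); names(genome) <- "chr"
        pos <- sample(80:120, 1)
        hit <- promoterBoxScan(genome, pos, "+", maxMismatches = 12)
        up <- substr(seqchr, pos - 60, pos - 1)
        expect_equal(hit$mismatches, oraclePromoterMinMismatch(up))
    }
})

test_that("planted TSSs are recovered end to end and PS sites never call", {
    fx <- smallFixture(seed = 2)
    sim <- simulateTaggedReads(fx$genome, fx$sites, fx$transcripts,
                               nReads = 30000, seed = 41)
    tracks <- simTracks(fx, sim)
    net <- subtractTracks(tracks$primary, tracks$processed)
    calls <- callTss(net, minCount = 10, mergeWindow = 3)
    expect_equal(siteRecovery(calls, fx$sites, "TSS"), 1)
    ps <- fx$sites[fx$sites$kind == "PS", ]
    for (i in seq_len(nrow(ps)))
        expect_false(any(abs(start(calls) - ps$position[i]) <= 1 &
                         as.character(strand(calls)) == ps$strand[i]))
    # a pure-processed library yields no TSS calls at all
    onlyPs <- fx$sites[fx$sites$kind == "PS", ]
    simPs <- simulateTaggedReads(fx$genome, onlyPs, NULL, nReads = 10000,
                                 internalFragmentFraction = 0, seed = 42)
    trPs <- simTracks(fx, simPs)
    netPs <- subtractTracks(trPs$primary, trPs$processed)
    expect_equal(length(callTss(netPs, minCount = 10)), 0L)
    # the intragenic precursor TSS is called, classified and assigned
    cls <- classifyTss(calls, fx$genes)
    int <- cls[mcols(cls)$category == "internal"]
    expect_equal(length(int), 1L)
    expect_equal(mcols(int)$gene, fx$precursorId)
    expect_equal(mcols(int)$utr_length, 348L)
})
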