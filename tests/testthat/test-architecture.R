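mkCalls <- function(pos, strand, gene, category = "gene_tss",
                    score = 50) {
    gr <- GRanges("chr", IRanges(pos, width = 1), strand = strand)
    mcols(gr)$tss_id <- sprintf("tss_%04d", seq_along(pos))
    mcols(gr)$score <- rep_len(score, length(pos))
    mcols(gr)$gene <- gene
    mcols(gr)$utr_length <- rep(30L, length(pos))
    mcols(gr)$category <- factor(rep_len(category, length(pos)),
        levels = c("gene_tss", "internal", "antisense", "orphan"))
    gr
}

test_that("terminators split units; weak ones become attenuators", {
    genes <- mkGenes(c(100, 600), c(400, 900), "+")
    tss <- mkCalls(80, "+", "g01")
    # no terminator between: one unit
    tu1 <- inferTranscriptionUnits(genes, tss, NULL)
    expect_equal(length(tu1), 1L)
    expect_equal(mcols(tu1)$gene_ids[[1]], c("g01", "g02"))
    # a strong terminator between: two units
    strong <- data.frame(term_id = "t1", position = 500, strand = "+",
                         delta_g = -18)
    tu2 <- inferTranscriptionUnits(genes, tss, strong)
    expect_equal(length(tu2), 2L)
    # a weak terminator between: one unit carrying an attenuator
    weak <- data.frame(term_id = "t1", position = 500, strand = "+",
                       delta_g = -9)
    tu3 <- inferTranscriptionUnits(genes, tss, weak)
    expect_equal(length(tu3), 1L)
    expect_equal(mcols(tu3)$attenuators[[1]], "t1")
    # wide gaps split even without a terminator
    far <- mkGenes(c(100, 1000), c(400, 1300), "+")
    expect_equal(length(inferTranscriptionUnits(far, tss, NULL)), 2L)
    # strand changes always split
    div <- mkGenes(c(100, 600), c(400, 900), c("+", "-"))
    expect_equal(length(inferTranscriptionUnits(div, tss, NULL)), 2L)
    expect_error(inferTranscriptionUnits(rev(genes), tss, NULL), "sorted")
    expect_error(inferTranscriptionUnits(genes, tss,
        data.frame(term_id = "t", position = 1, strand = "+",
                   delta_g = 2)), "negative")
})

test_that("the cluster fixture resolves to three units with one attenuator", {
    fx <- smallFixture(seed = 2)
    sim <- simulateTaggedReads(fx$genome, fx$sites, fx$transcripts,
                               nReads = 30000, seed = 51)
    tracks <- simTracks(fx, sim)
    calls <- classifyTss(callTss(subtractTracks(tracks$primary,
                                                tracks$processed)),
                         fx$genes)
    tus <- inferTranscriptionUnits(fx$genes, calls, fx$terminators)
    expect_equal(length(tus), 3L)
    g <- mcols(tus)$gene_ids
    expect_equal(g[[1]], "gene_A")
    expect_equal(g[[2]], "gene_B")
    expect_equal(g[[3]], paste0("gene_", LETTERS[3:13]))
    expect_equal(unlist(mcols(tus)$attenuators), "atten_DE")
    expect_equal(mcols(tus)$terminator[3], "term_M")
    # every gene belongs to exactly one unit, in genomic order
    expect_setequal(unlist(g), mcols(fx$genes)$gene_id)
    expect_equal(anyDuplicated(unlist(g)), 0L)
    # the operon's unit carries both its driving and its internal TSS
    expect_equal(length(mcols(tus)$tss_ids[[3]]), 2L)
})

test_that("precursor reports capture dedicated and intragenic TSSs", {
    fx <- smallFixture(seed = 2)
    sim <- simulateTaggedReads(fx$genome, fx$sites, fx$transcripts,
                               nReads = 30000, seed = 52)
    tracks <- simTracks(fx, sim)
    calls <- classifyTss(callTss(subtractTracks(tracks$primary,
                                                tracks$processed)),
                         fx$genes)
    tus <- inferTranscriptionUnits(fx$genes, calls, fx$terminators)
    rep <- precursorTssReport(fx$genes, calls, fx$precursorId, tus)
    expect_true(rep$dedicated_tss)
    expect_true(rep$intragenic)
    expect_equal(rep$utr_length, 348L)
    expect_equal(rep$tu_position, "internal")
    # report consistency with classification: intragenic iff internal
    intCall <- calls[!is.na(mcols(calls)$gene) &
                     mcols(calls)$gene == fx$precursorId]
    expect_equal(unname(rep$intragenic),
                 any(mcols(intCall)$category == "internal"))
    expect_error(precursorTssReport(fx$genes, calls, "nope"), "unknown")
})

test_that("a precursor at its unit's start is dedicated but not intragenic", {
    genes <- mkGenes(c(100, 600), c(400, 900), "+", c("pre", "tail"))
    calls <- mkCalls(60, "+", "pre", "gene_tss")
    tus <- inferTranscriptionUnits(genes, calls, NULL)
    rep <- precursorTssReport(genes, calls, "pre", tus)
    expect_true(rep$dedicated_tss)
    expect_false(rep$intragenic)
    expect_equal(rep$tu_position, "first")
    # and one with no assigned call at all
    rep2 <- precursorTssReport(genes, calls, "tail", tus)
    expect_false(rep2$dedicated_tss)
    expect_true(is.na(rep2$tss_position))
    # minus-strand units put the highest-coordinate gene first
    genesM <- mkGenes(c(100, 600), c(400, 900), "-", c("a", "b"))
    callsM <- mkCalls(950, "-", "b")
    tusM <- inferTranscriptionUnits(genesM, callsM, NULL)
    expect_equal(precursorTssReport(genesM, callsM, "b", tusM)$tu_position,
                 "first")
    expect_equal(precursorTssReport(genesM, callsM, "a", tusM)$tu_position,
                 "internal")
})

test_that("capture hits partition into shared and condition-specific blocks", {
    hits <- dacaFixture(nShared = 120, nProductionOnly = 177,
                        nControlOnly = 24, seed = 61)
    res <- dacaCandidateFilter(hits)
    expect_equal(unname(res$sizes), c(120L, 177L, 24L))
    expect_equal(sum(res$sizes), 321L)
    expect_equal(sum(res$sizes), nrow(hits))
    # candidates are production-only regulators/uncharacterized, in order
    expect_true(all(res$candidates$in_production &
                    !res$candidates$in_control))
    expect_true(all(res$candidates$annotation_class %in%
                    c("regulator", "uncharacterized")))
    expect_identical(res$candidates$protein_id,
                     intersect(hits$protein_id, res$candidates$protein_id))
    # degenerate and invalid inputs
    empty <- dacaCandidateFilter(hits[0, ])
    expect_equal(sum(empty$sizes), 0L)
    dup <- rbind(hits[1, ], hits[1, ])
    expect_error(dacaCandidateFilter(dup), "duplicate")
    bad <- hits[1, ]; bad$in_production <- FALSE; bad$in_control <- FALSE
    expect_error(dacaCandidateFilter(bad), "at least one condition")
})

test_that("the partition matches brute-force set algebra on random inputs", {
    set.seed(62)
    for (rep in 1:10) {
        n <- sample(5:60, 1)
        hits <- data.frame(
            protein_id = sprintf("Q%03d", seq_len(n)),
            in_production = sample(c(TRUE, FALSE), n, TRUE),
            in_control = sample(c(TRUE, FALSE), n, TRUE),
            annotation_class = sample(c("regulator", "uncharacterized",
                                        "other"), n, TRUE))
        keep <- hits$in_production | hits$in_control
        hits <- hits[keep, ]
        res <- dacaCandidateFilter(hits)
        want <- oracleDacaPartition(
            hits$protein_id[hits$in_production],
            hits$protein_id[hits$in_control])
        expect_setequal(
            res$partition$protein_id[res$partition$block == "shared"],
            want$shared)
        expect_setequal(
            res$partition$protein_id[res$partition$block ==
                                     "production_only"],
            want$production_only)
        expect_setequal(
            res$partition$protein_id[res$partition$block == "control_only"],
            want$control_only)
        expect_equal(sum(res$sizes), nrow(hits))
    }
})
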