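# Independent brute-force oracles. Deliberately naive (per-element loops,
# direct definitions) and kept free of the package's internals so that
# agreement with them is a real check.

oracleHamming <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    sum(av != bv)
}

oracleClassifyRead <- function(seq, primary, processed, maxMismatch) {
    k <- nchar(primary)
    if (nchar(seq) <= k) return("untagged")
    pre <- substr(seq, 1, k)
    isP <- oracleHamming(pre, primary) <= maxMismatch
    isQ <- oracleHamming(pre, processed) <= maxMismatch
    if (isP && isQ) "ambiguous" else if (isP) "primary"
    else if (isQ) "processed" else "untagged"
}

# per-position tally of 5' ends
oracleStartTrack <- function(pos, strand, L) {
    plus <- numeric(L); minus <- numeric(L)
    for (i in seq_along(pos)) {
        if (strand[i] == "+") plus[pos[i]] <- plus[pos[i]] + 1
        else minus[pos[i]] <- minus[pos[i]] + 1
    }
    list(plus = plus, minus = minus)
}

# depth by interval membership, one position at a time
oracleDepth <- function(starts, ends, L) {
    d <- numeric(L)
    for (p in seq_len(L)) d[p] <- sum(starts <= p & ends >= p)
    d
}

# read-to-gene assignment: scan genes in order, first same-strand span hit
oracleCounts <- function(pos, strand, gStart, gEnd, gStrand) {
    counts <- integer(length(gStart))
    intergenic <- 0L
    for (i in seq_along(pos)) {
        hit <- NA
        for (g in seq_along(gStart)) {
            if (gStrand[g] == strand[i] && gStart[g] <= pos[i] &&
                gEnd[g] >= pos[i]) { hit <- g; break }
        }
        if (is.na(hit)) intergenic <- intergenic + 1L
        else counts[hit] <- counts[hit] + 1L
    }
    list(counts = counts, intergenic = intergenic)
}

oracleSubtract <- function(p, q, clamp = TRUE) {
    out <- numeric(length(p))
    for (i in seq_along(p)) {
        d <- p[i] - q[i]
        out[i] <- if (clamp && d < 0) 0 else d
    }
    out
}

# spec rule, computed per position: sort each sample, average order
# statistics across samples, give each position the mean for its rank,
# averaging over its tied block
oracleQuantileNormalize <- function(M) {
    S <- apply(M, 2, sort)
    m <- rowMeans(S)
    out <- M
    for (j in seq_len(ncol(M))) {
        sorted <- sort(M[, j])
        for (i in seq_len(nrow(M))) {
            block <- which(sorted == M[i, j])
            out[i, j] <- mean(m[block])
        }
    }
    out
}

# exhaustive scan over all legal hexamer-pair placements in an upstream
# window (index 1 = farthest from the TSS, index length(up) adjacent);
# returns the minimum total mismatch count, or Inf if no legal placement
oraclePromoterMinMismatch <- function(up, gapRange = c(4, 9),
                                      spacerRange = c(15, 19),
                                      consensus35 = "TTGACA",
                                      consensus10 = "TATAAT") {
    n <- nchar(up)
    best <- Inf
    for (s35 in seq_len(n)) {
        for (s10 in seq_len(n)) {
            if (s35 + 5 > n || s10 + 5 > n) next
            spacer <- s10 - (s35 + 6)
            gap <- n - (s10 + 5)
            if (spacer < spacerRange[1] || spacer > spacerRange[2]) next
            if (gap < gapRange[1] || gap > gapRange[2]) next
            mm <- oracleHamming(substr(up, s35, s35 + 5), consensus35) +
                oracleHamming(substr(up, s10, s10 + 5), consensus10)
            if (mm < best) best <- mm
        }
    }
    best
}

# partition by plain set algebra on id vectors
oracleDacaPartition <- function(prodIds, ctrlIds) {
    list(shared = intersect(prodIds, ctrlIds),
         production_only = setdiff(prodIds, ctrlIds),
         control_only = setdiff(ctrlIds, prodIds))
}
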