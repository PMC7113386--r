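# tagTSS

Transcription start site discovery from bacterial 5'-tag RNA-seq
(tagRNA-seq), in R / Bioconductor style.

## The problem

A bacterial transcript 5' end is either *primary* (5'-triphosphate, the
exact position where RNA polymerase initiated — a true transcription
start site, TSS) or *processed* (5'-monophosphate, left behind by RNase
cleavage or degradation — a processing site, PS). tagRNA-seq labels the
two chemistries with distinct ligated sequence tags (`CTGAAGCT` for
processed ends; then, after polyphosphatase conversion, `TAATGCGC` for
primary ends), so the distinction survives into the reads. This matters
wherever a promoter map has to be trusted at single-nucleotide
resolution — for example in ribosomally synthesized peptide (RiPP)
biosynthetic gene clusters, where a precursor-peptide gene buried
mid-operon can carry its own intragenic TSS that selectively boosts its
transcription relative to the surrounding catalytic genes.

tagTSS is for people analyzing such libraries (or prototyping the
analysis): it demultiplexes and trims tagged reads, turns SAM
alignments into strand-specific per-nucleotide 5'-end **start tracks**
and depth tracks, quantile-normalizes tracks across samples, computes
the *primary minus processed* net track, and calls and classifies TSSs.
Around that core it quantifies expression (gene counts, RPKM, TPM,
genome-wide ranks), infers transcription units with
terminator/attenuator annotation, reports the TSS architecture of
precursor-peptide genes, scans sigma-70 promoter boxes, and filters
DNA-affinity-capture (DACA) protein hits for candidate regulators. A
fully ground-truthed read simulator ships with the package, so every
stage is testable against known truth.

## The method in one paragraph

With $P_s(x)$, $Q_s(x)$ the accepted primary/processed read 5'-end
counts at position $x$ on strand $s$: rank-average quantile-normalize
each class across samples (per strand, full genome vectors); form the
net track $N_s(x) = \max(0, P_s(x) - Q_s(x))$; call TSSs where
$N_s(x) \ge$ `minCount` (default 10), merging same-strand candidates
within 3 nt to the signal maximum; assign each call to the nearest
same-strand gene starting downstream within 500 nt, classifying it as
`gene_tss`, `internal` (intragenic), `antisense` or `orphan`, with
5'UTR length (TSS base counted) and leadered class (leaderless < 10 nt,
extended-leadered > 100 nt). RPKM is
$c / ((\ell/10^3)(T/10^6))$ for count $c$, gene length $\ell$, total
mapped reads $T$; TPM rescales length-normalized rates to sum to
$10^6$.

## Worked example

Simulate the default study conditions — a 100 kb genome with a 13-gene
bottromycin-like cluster (the precursor gene's TSS planted inside the
preceding gene) plus 20 background genes, and a 200k-read library —
then run the pipeline:

```r
library(tagTSS)

fx  <- generateGenome(length = 1e5, nGenes = 33, seed = 1)
sim <- simulateTaggedReads(fx$genome, fx$sites, fx$transcripts,
                           nReads = 2e5, seed = 2)
paths <- writeSimulatedReads(sim, "lib1")

demuxFastq(paths[["fastq"]], tagSpec(), outPrefix = "lib1")$counts
#>   primary processed  untagged ambiguous
#>     69093     21675    109232         0
```

About a third of the reads carry the primary tag, a tenth the processed
tag, and half are untagged transcript-body fragments. Build the start
tracks from the alignments and call TSSs:

```r
aln <- readSam(paths[["sam"]])
cls <- classifyReads(ShortRead::sread(sim$reads))
byId <- setNames(as.character(cls$tag_class),
                 as.character(ShortRead::id(sim$reads)))
qn  <- S4Vectors::mcols(aln)$qname
pri <- buildStartTrack(aln[byId[qn] == "primary"],   1e5, "primary",   "wt")
pro <- buildStartTrack(aln[byId[qn] == "processed"], 1e5, "processed", "wt")

calls <- classifyTss(callTss(subtractTracks(pri, pro), minCount = 10),
                     fx$genes)
head(as.data.frame(calls)[, c("start", "strand", "score", "gene",
                              "utr_length", "category", "leadered_class")])
#>   start strand score   gene utr_length category    leadered_class
#> 1  5939      -  1455 gene_A         40 gene_tss          leadered
#> 2  6969      -  2000 gene_B         70 gene_tss          leadered
#> 3  7068      +  3704 gene_C         32 gene_tss          leadered
#> 4  8134      +  5103 gene_D        348 internal extended_leadered
#> 5 18450      +   527  bg_01         50 gene_tss          leadered
#> 6 21949      -   719  bg_02         50 gene_tss          leadered
```

Every call sits exactly on a planted TSS; none of the ten planted
processing sites is called, because the processed track cancels them in
the subtraction. The fourth row is the interesting one: a TSS inside
`gene_C` but assigned to the precursor gene `gene_D`, 348 nt upstream
of its start codon — an extended-leadered intragenic start, the
architecture the method exists to detect. The architecture screen
summarizes it directly:

```r
tus <- inferTranscriptionUnits(fx$genes, calls, fx$terminators)
precursorTssReport(fx$genes, calls, fx$precursorId, tus)
#>   precursor_id dedicated_tss intragenic tss_position utr_length tu_id tu_position
#> 1       gene_D          TRUE       TRUE         8134        348 TU_03    internal
```

The cluster resolves into three transcription units ({A}, {B}, {C..M}),
the intra-operon terminator between `gene_D` and `gene_E` is annotated
as an attenuator rather than a unit boundary, and the planted consensus
promoter upstream of the operon's main TSS is recovered with zero
mismatches and a 17 nt spacer:

```r
promoterBoxScan(fx$genome, 7068, "+")
#>   minus35 minus35_pos minus35_mismatches minus10 minus10_pos minus10_mismatches spacer gap mismatches
#> 1  TTGACA        7032                  0  TATAAT        7055                  0     17   7          0
```

## Package tour

| area | functions |
|---|---|
| simulation | `generateGenome`, `simulateTaggedReads`, `writeSimulatedReads` |
| demultiplexing | `tagSpec`, `classifyReads`, `demuxFastq` |
| tracks | `readSam`, `fivePrimePositions`, `buildStartTrack`, `buildDepthTrack`, `writeWig`/`readWig`, `writeBedGraph`/`readBedGraph`, `writeStartTrack`/`readStartTrack` |
| TSS calling | `quantileNormalizeTracks`, `subtractTracks`, `callTss`, `classifyTss`, `promoterBoxScan` |
| expression | `countReadsPerGene`, `rpkm`, `tpm`, `rankGenes`, `expressionTable` |
| architecture | `inferTranscriptionUnits`, `precursorTssReport`, `dacaCandidateFilter`, `dacaFixture` |

The methods vignette (`vignettes/tagTSS-methods.Rmd`) documents the
model, the defaults and their rationale, what the simulator does and
does not emulate, and known limitations.
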