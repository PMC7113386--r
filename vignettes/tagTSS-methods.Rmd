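---
title: "Mapping transcription start sites with tagTSS: methods and design"
author: "tagTSS maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcription start sites with tagTSS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(tagTSS)
  library(GenomicRanges)
})
```

## The problem and the measurement

A bacterial RNA 5' end comes in two chemistries. Primary transcripts --
RNA exactly as initiated by RNA polymerase -- carry a 5'-triphosphate;
transcripts that have been cleaved or partially degraded carry a
5'-monophosphate. A naive 5'-end sequencing experiment cannot tell a
transcription start site (TSS) from an RNase processing site (PS).

5'-tag RNA-seq (tagRNA-seq) resolves this at the bench: a first sequence
tag (`CTGAAGCT`) is ligated to the 5'-monophosphate ends present in the
sample (the processed ends); a polyphosphatase then converts
5'-triphosphates to ligatable monophosphates and a second tag
(`TAATGCGC`) marks those primary ends. After fragmentation and standard
library construction, a read beginning with a tag pinpoints a 5' end of
known chemistry at single-nucleotide resolution, while untagged reads
sample transcript bodies and preserve whole-transcriptome coverage.

tagTSS implements everything downstream of the sequencer: tag
demultiplexing and trimming, strand-specific 5'-end "start tracks" from
SAM alignments, cross-sample quantile normalization, subtraction of the
processed signal from the primary signal, TSS calling and annotation,
expression quantification (counts, RPKM, TPM, ranks), transcription-unit
inference with attenuator annotation, a genome-wide screen of
precursor-peptide gene TSS architecture, and the condition-contrast
filter used for DNA-affinity-capture (DACA) candidate regulators.

## The core computation

For one sample, let $P_s(x)$ and $Q_s(x)$ be the number of accepted
primary- and processed-tagged read 5' ends at genomic position $x$ on
strand $s$ (a `StartTrack` per class). The pipeline is:

1. **Normalize.** Rank-average quantile normalization is applied per
   strand across samples, within each transcript class, to remove
   sequencing-depth differences: each sample's vector is sorted, order
   statistics are averaged across samples at each sort index, and every
   position receives the mean for its rank. A tied block receives the
   average of the rank means across the block. Normalization runs on the
   full genome-length vectors (which are dominated by zeros); restricting
   it to nonzero positions would change the result, so we do not.
2. **Subtract.** The net track is $N_s(x) = \max(0, P_s(x) - Q_s(x))$
   ("wig minus wig"). Clamping at zero is deliberate: an excess of
   processed over primary signal carries no TSS information. An unclamped
   difference is available for diagnostics.
3. **Call.** Positions with $N_s(x) \ge$ `minCount` are candidates;
   same-strand candidates within `mergeWindow` nt merge into one call at
   the maximum-signal position (ties resolve to the smallest
   coordinate).
4. **Classify.** Each call is assigned to the nearest same-strand gene
   whose start codon lies downstream within `maxUpstream` nt. A call
   that also lies inside another same-strand gene is *internal* (an
   intragenic TSS); a call inside an opposite-strand gene with no
   same-strand assignment is *antisense*; anything else unassigned is an
   *orphan*. The 5'UTR counts the TSS base as transcribed
   (`utr = gene start - position` on the plus strand), so a TSS on the
   start codon has UTR 0.

The subtraction step is what makes the method discriminative: at a
processing site the processed signal dwarfs any stray primary signal
(mistagging is a percent-level effect), so the clamped difference
vanishes; at a genuine TSS the primary signal survives essentially
intact.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `maxMismatch` (tags) | 0 | nt | exact tag matching is the conservative reading of the protocol; the two tags differ at all 8 positions, so tolerances up to 3 stay unambiguous |
| `max5pSoftclip` | 3 | nt | a read whose 5' side did not align no longer marks a transcript start; small clips tolerate ragged ends |
| `minCount` | 10 | normalized read units | the calling threshold on the net track; there is no published operational value, so this is a tunable with a deliberately modest default |
| `mergeWindow` | 3 | nt | transcription initiation is often ragged over 1-3 nt; merging keeps one call per promoter |
| `maxUpstream` | 500 | nt | accommodates long 5'UTRs (the motivating cluster has a 348 nt case) without swallowing unrelated upstream genes |
| `leaderlessMax` | 10 | nt | UTRs shorter than this leave no room for a ribosome binding site |
| `extendedMin` | 100 | nt | lower bound of the usual 100-150 nt "extended-leadered" convention; such UTRs are candidates for cis-regulatory elements |
| `splitThreshold` | -15 | kcal/mol | terminators at or below this free energy split transcription units; weaker ones are annotated as attenuators |
| `maxGap` | 300 | nt | same-strand genes farther apart than this are not co-transcribed by default |

Transcription-unit inference deserves a caveat: the underlying evidence
for operon joins in the motivating study is RT-PCR, not a computable
rule. Our rule -- split at strand changes, wide gaps and strong
terminators; annotate surviving internal terminators as attenuators;
never split at an internal TSS -- is an explicit model with tunable
parameters, validated against fixtures with known architecture, not a
re-derivation of the published operon map.

The promoter-box scanner is annotation plumbing, not a promoter
predictor: it exhaustively scores -35/-10 hexamer pairs against the
sigma-70 consensus (`TTGACA`/`TATAAT`) with a 15-19 nt spacer and a
4-9 nt gap to the TSS, and reports the best placement (ties prefer a
17 nt spacer). It replaces an external prediction tool in the pipeline
and makes no strength claim.

## The synthetic-data generator

Because the real deposited libraries cannot be reanalyzed at desk
scale, the package ships a ground-truthed simulator, and all
whole-method validation runs against it.

`generateGenome()` builds a random high-GC genome (GC fraction 0.71, a
*Streptomyces*-like composition) carrying a 13-gene cluster that
reproduces the geometry of interest: two divergent minus-strand genes,
then a tightly packed 11-gene plus-strand run whose second gene is the
designated precursor-peptide gene. The precursor's dedicated TSS is
planted 348 nt upstream of its start codon, inside the preceding gene
and 215 nt before that gene's end. A consensus promoter is planted
upstream of the run's first TSS. Beyond the cluster, background genes
(alternating strands, one TSS each, strengths spanning 20-200 expected
reads) and interleaved processing sites fill the genome. Intrinsic
terminator records are emitted alongside: strong terminators flank the
cluster's three transcription units, and the intra-operon terminator
between the precursor gene and its successor is written with a free
energy of -12 kcal/mol -- above the split threshold -- together with a
read-through fraction of 0.3, reflecting its role as an attenuator that
dampens but does not abolish downstream transcription.

`simulateTaggedReads()` draws per-site read counts as Poisson variables
around the site strengths. When a library size `nReads` is given (the
default conditions use 200,000 reads), strengths are first rescaled so
that tagged reads form `1 - internalFragmentFraction` of the library and
the emitted read count is exact; with `nReads = NULL` strengths are used
as absolute expected counts and the library size emerges. Each 5' end
receives its correct tag with probability `tagEfficiency` (default
0.9), the wrong tag with probability `mistagRate` (default 0.01, a
percent-level ligation error), and no tag otherwise. Untagged internal
fragments start uniformly within transcript bodies, with density
multiplied by the read-through fraction downstream of each attenuator.
Minus-strand reads are emitted as reverse complements with the tag at
the read's 5' end, exactly as a sequencer would deliver them, so
demultiplexing never needs to know the strand. Reads are 75 nt after
the tag, with constant Q40 qualities; the error-free truth alignment of
every trimmed read is emitted as SAM, which stands in for the aligner
(alignment itself is out of scope).

One deliberate departure from the random-genome model: the generator
mutates one base inside every exact occurrence of either 8 nt tag in
the genome (about six are expected per 100 kb per the 4^-8 motif
probability). Without this, an untagged fragment can begin with a
genomic tag look-alike and demultiplexing is not exactly invertible
even in principle; with it, the simulator's truth table is recoverable
read-for-read, which is what the demultiplexing exactness check
asserts.

What the simulator does *not* emulate -- and what passing tests
therefore do not establish about real data: sequencing errors are off
by default (a uniform substitution model exists for robustness tests
only, and never touches the tag bases); there is no rRNA carryover, no
coverage bias along transcripts, no paired-end information, and the
aligner is assumed perfect because its output is the simulator's truth.
Real libraries will show lower sensitivity at weak TSSs and ragged call
positions; the defaults here (`minCount = 10`, site strengths at least
20 expected reads, sites at least 50 nt apart) describe a regime where
recovery should be essentially complete, and the tests confirm exactly
that.

In the fixture, every transcription unit's head gene carries a planted
TSS, including the first of the two divergent genes. The motivating
experiment found no TSS for the corresponding gene, which remains an
open observation there; a unit without any start would make the
fixture's architecture unrecoverable from the data alone, so the
synthetic truth is the idealized version.

## Numerical choices

* **Quantile-normalization ties.** Tied values receive the average of
  the rank means over their tied block. Since genome-length tracks are
  mostly zeros, the zero block is huge and this choice matters; the
  alternative (interpolating at the mean rank, as some implementations
  do) gives different values on ties. On tie-free input the two agree
  and the classic invariant holds exactly: all samples share one sorted
  value vector afterwards. With unequal tie structures that identity is
  only approximate, which is why the contract tests use continuous
  values.
* **Track serialization.** Wiggle (1-based, variableStep) and bedGraph
  (0-based half-open, equal-value runs merged) writers print doubles
  with 17 significant digits, so write-then-read is an exact identity
  on any track, normalized or not.
* **Coordinates.** Everything internal is 1-based and inclusive;
  bedGraph is converted at the file boundary only.
* **Degenerate inputs.** An all-zero count vector yields all-zero TPM
  (not NaN); an empty FASTQ demultiplexes to three empty files; a
  single sample is a fixed point of normalization; `callTss` on an
  all-zero net track returns an empty `GRanges`.
* **Tie-breaks.** Merged TSS peaks resolve to the smallest coordinate
  at equal signal; tied TPM values share the minimum rank (a tie for
  4th reports two genes at rank 4); promoter placements tie-break by
  spacer closeness to 17 nt, then smaller gap.

## Problem sizes

The shipped validation runs at the default study conditions: a 100 kb
genome, 33 genes (13 cluster + 20 background), 24 planted TSSs and 10
processing sites, libraries of 200,000 reads, and two replicate samples
for the normalization step. These sizes make every whole-method check
run comfortably on a laptop while keeping all the geometric features --
the intragenic precursor TSS, the attenuator, divergent gene pairs,
strand-alternating background -- that the classifier and the
architecture screen have to get right.

## Known limitations

* Transcription-unit inference is a parameterized model (see above);
  its defaults are sensible for actinobacterial genomes but are not
  fitted to data.
* Read counting assigns a read to the gene containing its 5'-most
  aligned base. This is deterministic and never double-counts across
  overlapping genes, but it differs from span-overlap counting
  (available via `countMode = "span-overlap"`) for reads straddling a
  gene boundary; the published analysis does not state its rule.
* RPKM uses all accepted alignments (intergenic included) as the
  library size; tools that use only gene-assigned reads will scale
  differently.
* The 5'UTR convention counts the TSS base as transcribed. Off-by-one
  conventions exist in the literature (the motivating study itself
  prints both 348 and 347 for the same UTR); we use one convention
  everywhere and do not attempt to reproduce both numbers.
* The DACA filter reproduces the set logic of the condition contrast;
  which proteins count as "regulator" or "uncharacterized" is an
  annotation input, so the final shortlist length on real data depends
  on annotation calls the package does not model.

## A minimal run

```{r pipeline, eval = FALSE}
fx <- generateGenome(length = 1e5, nGenes = 33, seed = 1)
sim <- simulateTaggedReads(fx$genome, fx$sites, fx$transcripts,
                           nReads = 2e5, seed = 2)
paths <- writeSimulatedReads(sim, "library1")

dm <- demuxFastq(paths[["fastq"]], tagSpec(), outPrefix = "library1")
aln <- readSam(paths[["sam"]])

cls <- classifyReads(ShortRead::sread(sim$reads))
byId <- setNames(as.character(cls$tag_class),
                 as.character(ShortRead::id(sim$reads)))
qn <- S4Vectors::mcols(aln)$qname
pri <- buildStartTrack(aln[byId[qn] == "primary"], 1e5, "primary", "wt")
pro <- buildStartTrack(aln[byId[qn] == "processed"], 1e5, "processed", "wt")

net <- subtractTracks(pri, pro)
calls <- classifyTss(callTss(net, minCount = 10), fx$genes)
tus <- inferTranscriptionUnits(fx$genes, calls, fx$terminators)
precursorTssReport(fx$genes, calls, fx$precursorId, tus)
```
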