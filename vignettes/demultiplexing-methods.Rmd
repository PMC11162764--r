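---
title: "Methods: demultiplexing and consensus assembly of barcoded plasmid arrays"
author: "PlasmidArray authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demultiplexing and consensus assembly of barcoded plasmid arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PlasmidArray)
```

## The problem

Arrayed in vivo barcoding joins a short positional DNA barcode — whose
identity encodes a plate/well address — to a plasmid of interest inside the
cell, so that whole arrays of clones can be pooled for a single plasmid
extraction and a single long-read (Oxford Nanopore style) library
preparation. Sequencing then has to be undone computationally: every read
must be routed back to the well it came from, and each well's reads
condensed into one polished consensus sequence that can be declared pure (a
single clone) and correct (identical to its intended reference).

`PlasmidArray` implements that analysis as a set of composable stages with a
single driver, `runArrayPipeline()`:

1. size filtering of raw reads;
2. sample-index demultiplexing (exact match, both orientations);
3. fuzzy, flank-anchored extraction of the positional barcode;
4. greedy edit-distance clustering of barcode observations and assignment to
   a known plate map;
5. binning of reads per (sample, position), with an unbinned sink so that no
   read is silently lost;
6. trimming of each read to the insert between two known flanks;
7. optional splitting of heterogeneous wells by a read-length Gaussian
   mixture;
8. star-alignment consensus, iterative polishing;
9. purity and correctness calls;
10. array-level recovery/accuracy with bootstrap standard errors, plus pool
    dispersion statistics.

A fully ground-truthed synthetic generator (`buildArrayRun()`) makes every
stage testable end to end without external data.

## Barcode extraction

Positional barcodes sit in a fixed sequence context. A
`BarcodeDefinition` holds the two flanks, the admissible core length range,
optional internal motif constraints, and a per-flank Levenshtein edit budget
(`maxFlankEdits`, default 2). Extraction locates each flank at the smallest
edit budget that yields a hit (0, then 1, ... up to the budget), leftmost
among hits at that budget, on the forward strand first and then on the
reverse complement. The intervening core is returned when its length is in
range and motifs are satisfied. The tie-break order — fewest edits, then
leftmost, then forward strand — is fixed so extraction is deterministic.

The edit budget of the original fuzzy-regex extraction is not documented
anywhere we could find, so 2 is a default, not a fact; it keeps the
false-location rate negligible for 20-nt flanks while tolerating the typical
1–2 errors such flanks accumulate at long-read error rates. For the
short-read (Illumina-style) path the two published extraction patterns are
applied verbatim (`barcodePatterns`, `extractBarcodeRegex()`); they encode
their own fuzziness and are deliberately not re-interpreted.

## Clustering and assignment

Observed barcode cores are collapsed by greedy count-ordered clustering
(`clusterBarcodes()`): unique sequences sorted by descending count (ties
lexicographic), each joining the first cluster whose centroid is within
`maxDist` Levenshtein edits, else founding a new cluster. This is the
behaviour class of the standard barcode clusterers; their exact
message-passing/sphere-removal internals are out of scope, and the greedy
scheme is simple enough to verify against a step-by-step oracle in the test
suite. `maxDist` defaults to 2 for cores up to 16 nt and 3 for longer cores
(the published tool's setting is unstated; this is logged as a default).
Cluster centroids are then assigned to the plate map's known barcodes at the
same radius; a centroid equidistant from two known barcodes is left
unassigned and flagged, never guessed.

UMI deduplication (`dedupUMIs()`) is exact-match within a barcode pair —
the published method removes replicate UMIs rather than building
error-correction networks — and the chimera filter (`filterPairCounts()`)
applies the strict printed rule: pairs with fewer than 20 reads are removed,
a pair with exactly 20 is kept.

## Consensus building

Reads are first trimmed to the insert between two known trimming flanks
(same fuzzy machinery, orientation-normalising). The consensus is then a
star alignment: the medoid read (minimum summed edit distance to a
deterministic, evenly spaced subsample of 15 reads) serves as the template;
every read is globally aligned to it at unit costs; and each template column
takes a plurality vote over {A, C, G, T, gap}. Votes tie toward the current
template base (stability), then lexicographically, with the gap symbol
losing ties. Insertions are accepted at a junction only when a strict
majority of reads inserts there. Polishing repeats this vote against the
current consensus until a fixed point or `maxIter = 5`; the `converged` flag
records which. A full multiple-sequence alignment is deliberately replaced
by the star alignment: at the depths involved (tens to ~100 reads of a few
hundred nt) the column votes agree and the cost stays O(n L^2).

Consensus cost is bounded by a per-bin read cap (default 100), keeping the
most length-concordant reads (closest to the median length) — a cheap,
deterministic proxy for "reads that span the whole insert". For circular
sequences, `rotateCanonical()` makes assemblies comparable: rotation to a
fuzzily located anchor when one is given, else the lexicographically minimal
rotation, which is invariant across input rotations by construction.

"End-to-end identity" is fixed as `1 - Levenshtein(a, b) / max(|a|, |b|)`
(two empty strings: 1; exactly one empty: 0) and used consistently for
purity, correctness and assignment throughout the package.

## Purity and correctness

A position's purity is the fraction of its trimmed reads with identity at or
above 0.90 to the position's consensus; a position is called pure iff it has
at least 5 reads and purity at or above 0.90. Both thresholds are applied
inclusively: the source protocol states the rule both as "at least 90%" and
as ">90%", and the inclusive reading is adopted everywhere (the discrepancy
is recorded rather than resolved per-call). Purity is computed over trimmed
reads — reads whose trimming flanks cannot be located never reach the
identity comparison, since an untrimmable read says nothing about clone
mixture.

Correctness classifies the consensus against the reference set: exact
equality to the best-identity reference is `perfect`; identity at or above
`mapThreshold` (default 0.80; no published value exists for this boundary)
is `error`, with substitution/insertion/deletion counts taken from the
alignment; otherwise `off_target` when the consensus maps to a supplied
host genome at that threshold (local alignment), else `other`. Impure
positions are `mixed` by construction.

For array-level scoring, a known position counts as *detected* when it
yields a pure call — the reference workflow attributes missing positions to
insufficient coverage, and an impure position is not a usable detection —
and a detection is *correct* when its consensus matches a reference
perfectly (and, when ground truth is supplied, the matched reference is the
design expected at that position). Recovery is detected/known, accuracy is
correct/detected (flagged undefined, and reported as 0, when nothing is
detected); standard errors come from bootstrapping positions
(`bootstrapSE()`, B = 1000).

## Heterogeneous wells

Wells holding two plasmid species of different sizes are separated by a 1-D
Gaussian mixture on read lengths (`splitByLengthGMM()`): EM with
quantile-based initialisation, tolerance 1e-6, at most 200 iterations;
component count selected by BIC over k = 1..3, rejecting any fit with an
effectively empty component. All of these are defaults chosen here — the
source pipeline names the model but none of its controls. Bins under 10
reads are never split (a mixture fit on fewer points is noise), and the
consensus is built from the largest length cluster while purity is still
scored over all trimmed reads, so same-length mixtures — which no length
model can separate — surface as impure rather than as confident miscalls.

## Pool dispersion statistics

`giniCoefficient()` uses the population mean-absolute-difference form
(via the sorted-vector identity), so a uniform pool gives exactly 0 and a
single-spike pool approaches (n-1)/n; the sample (n-1) variant would break
the "uniform = 0" anchor. `expectedRecovery()` assumes sampling with
replacement at the empirical design frequencies: with N = depth × n draws,
the expected recovered fraction is mean(1 - (1 - p_i)^N). The in silico
sampling procedure behind the published recovery curves is not further
specified; independent multinomial draws are the natural null model.
`expectedErrorFraction()` is the synthesis-error prediction 1 - (1 - r)^L;
`substitutionErrorRate()` counts alignment substitutions per aligned
reference base; `abundanceCorrelation()` is plain Pearson on raw counts with
t-distribution significance (whether the published correlations were on raw
or normalised abundances is unstated; raw is used and documented).

## The synthetic world

`simConfig()` defaults state the simulated world once:

* `synthesisErrorRate = 4e-4`/nt — the vendor-reported oligonucleotide
  synthesis error rate (i.i.d. substitutions; synthesis indels are not
  modelled separately, since every downstream consumer sees only "clone
  differs from design").
* `designLength = 300` nt — the oligonucleotide pool design size.
* `meanDepth = 130` — reads per position, as Poisson; the empirical
  well-to-well depth distribution is unpublished, so Poisson is an explicit
  assumption, not a fact.
* `readErrorRates = (0.02, 0.015, 0.025)` substitution/insertion/deletion
  per base — an ONT-simplex-like profile of roughly 6% total error, chosen
  once as realistic for recent simplex basecalls. No homopolymer,
  quality-score or signal-level structure is modelled; accordingly the
  pipeline's purity rule is identity-based, and green tests say nothing
  about quality-aware processing.
* reads are emitted forward or reverse-complement with probability 0.5, so
  every downstream stage must be strand-agnostic (and is tested as such).
* sample indices are written error-free: they stand in for the
  instrument-side demultiplexing tags the real pipeline consumes as called;
  modelling index miscalls would test the instrument, not this package.
* contamination mixes two clones at a uniform [0.1, 0.9] ratio; chimeras are
  barcode-swap events only, matching the level at which the published
  chimera filter operates (barcode-pair counts), not mid-insert fusions.
* barcode sets are rejection-sampled to a minimum pairwise Hamming distance
  with an attempt budget of 1000 × n, failing loudly rather than silently
  relaxing the constraint.

Design abundances follow a log-normal with sigma equal to the
`abundanceDispersion` knob: a single parameter that reproduces the
long-tailed dispersion seen in real pools, with sigma 0 giving an exactly
uniform pool. What a green end-to-end test establishes is therefore: the
code paths recover a stated, plausible world — not that the error model
reproduces any particular flow cell.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open in all extraction outputs.
* Edit distances are unit-cost Levenshtein, computed in a small C++ core
  (banded with early abandon where a cap applies); `utils::adist` serves as
  the independent oracle for it in the tests, and supplies the alignment
  traces used for consensus column votes.
* Empty inputs: zero reads make purity an error (not 0); an empty FASTQ
  yields an empty report, not a crash; an all-zero abundance vector is an
  error for Gini.
* Determinism: every stochastic operation takes a seed and restores the
  caller's RNG state; identical config + seed reproduces byte-identical
  simulator output.

## Limitations

Signature-sequence (alignment-based) species separation is subsumed by the
length mixture and reference classification rather than implemented as a
separate alignment stage. De novo assembly of long (>1 kb) multi-species
plasmids is out of scope — the same consensus machinery is applied to
trimmed inserts instead. Host-genome mapping for off-target calls uses local
pairwise alignment and is intended for fixture-scale genomes, not
chromosome-scale references. Known-contaminant read filtering is not
implemented.
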