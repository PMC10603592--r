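---
title: "Methods: canonical k-mer indexing for reference-free pangenome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical k-mer indexing for reference-free pangenome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerpan)
```

## The model

kmerpan represents a pangenome without a reference genome, a coordinate
system, or any alignment. A set *G* of input genomes is decomposed into the
set *K* of all distinct **canonical k-mers** observed in at least one
genome, and the pangenome is the |K| × |G| binary table *X* recording which
genomes contain each k-mer. Every class of variation that adds or removes a
k-mer — SNPs, INDELs, and structural variants — leaves a footprint in this
table, and because membership is per-genome rather than per-position, the
representation is indifferent to assembly contiguity: chromosomes, contig
sets and unaligned reads index identically up to the k-mers that span
contig junctions.

A k-mer and its reverse complement are the same molecule observed from
opposite strands, so each window is recorded in **canonical form**: the
lexicographically smaller of the window and its reverse complement. Under
the packed 2-bit encoding used here (A=0, C=1, G=2, T=3, 5'-most base in
the most significant bits), lexicographic order on strings coincides with
integer order on codes, so canonicalization is `min(code, revcomp(code))`.
For odd k no k-mer can equal its own reverse complement, so the canonical
code space has exactly 4^k / 2 elements; this is why k is restricted to
odd values. The package verifies the 4^k/2 cardinality exhaustively for
k = 3 and k = 5 in its test suite.

### Choice of k

The default is **k = 31**. A 31-mer packs into 62 bits of a 64-bit
integer, is long enough that chance collisions between unrelated genomic
positions are rare (4^31 ≈ 4.6 × 10^18 possible codes), and is short
enough to tolerate moderate divergence between genomes. Smaller odd k
(down to 3) is supported and useful for toys and tests. k > 31 would
require 128-bit codes and is out of scope.

A precision note specific to R: R has no native 64-bit integer type.
Inside an index, codes are held as raw little-endian 8-byte units and all
arithmetic happens in compiled code, so every supported k is exact end to
end. The convenience functions that expose codes as R numerics
(`kmer_encode()`, `kmer_extract()`'s `code` column) are exact only up to
k = 26 (codes < 2^53); above that the numeric view may round low bits,
which is why `kmer_extract()` also returns the exact k-mer string decoded
in compiled code, and why the index pipeline never round-trips codes
through R doubles.

### Windows with ambiguity codes

Any window containing a character other than A/C/G/T (N runs, IUPAC
ambiguity codes, gaps) is skipped entirely — ambiguity is never expanded
into alternative k-mers, and soft-masked lowercase is uppercased since
masking carries no information for presence/absence. In conservation
tracks these skipped windows are *missing*, not zero, so N-gaps do not
masquerade as variable sequence.

## Segmented, memory-bounded construction

The theoretical canonical code space [0, 4^k) is tiled into `n_segments`
equal-width, contiguous, half-open ranges (the last segment absorbs the
remainder). Construction proceeds as one round per segment: all genomes
are scanned, k-mers outside the segment are skipped, and the segment's
sub-table is assembled; sub-tables concatenate in segment order into the
final index. Because segment membership is a pure range test on the code,
the result is **bit-identical for every segmentation**, and peak memory
for the k-mer table scales with the largest segment rather than with |K|.
This invariance is tested across `n_segments` ∈ {1, 2, 8, 64}.

Within a segment, each genome's codes are sorted and deduplicated, the
row set is their sorted union, and presence bits are filled by a linear
merge — no hash tables, so merges are deterministic and memory
predictable. Genomes are scanned sequentially in the order supplied; that
order is the column order of the index and of every downstream matrix,
and is recorded verbatim in the index metadata. A `threads` argument is
accepted for interface compatibility, but rounds execute sequentially:
determinism is the contract, and at the scales this package targets the
compiled scan is not the bottleneck.

The presence table stores multiplicity-free binary values only. This is a
deliberate limitation: copy-number differences inside repeat families are
invisible to the index, and locus-level interpretation leans on the
approximation that a given k-mer occurs about once per genome — sound for
k = 31 outside of high-copy repeats.

## On-disk format

The `.pki` file is: 4 magic bytes `KPAN`; a little-endian int32 format
version (currently 1); a little-endian int32 metadata length; a JSON
metadata block (k, genome ids in column order, contig table, row count,
per-genome distinct-k-mer counts); the sorted code array as |K|
little-endian unsigned 64-bit integers; and the presence block, one row
per k-mer of ceiling(|G|/8) bytes with genome *g* at byte `g %/% 8`, bit
`g %% 8`. Total file length is implied by the metadata, which is how
truncation and trailing bytes are detected; unknown magic or version is
an explicit incompatibility error. Write-then-read is bit-identical, and
the format is versioned and repo-defined — no byte compatibility with any
other tool's files is claimed.

## Pairwise statistics

With column k-mer sets K_i, the base statistic is the shared count
|K_i ∩ K_j| computed by bitwise column intersection. Derived statistics:

* **Jaccard**: J = |K_i ∩ K_j| / |K_i ∪ K_j|. Undefined (reported `NA`,
  never 0) when a genome has no k-mers.
* **ANI**: the Mash transform ANI% = 100 · (1 + ln(2J/(1+J)) / k),
  clamped below at 0, `NA` at J = 0 where the transform diverges. The
  literature contains several k-mer→ANI mappings; the Mash transform is
  the established default for Jaccard input and is stated here
  prominently because second-decimal ANI values depend on this choice.
* **QV** (MerQury-style): the query→reference completeness
  c = |K_i ∩ K_j| / |K_i| gives a per-base error estimate
  E = 1 − c^(1/k) and QV = −10·log10(E). Perfect agreement (E = 0) is
  reported as the finite, sortable cap 99; zero sharing gives QV 0. The
  **symmetric variant** replaces |K_i| with |K_i ∪ K_j|, which is
  symmetric by construction and coincides with the directional value when
  the two sets are identical.

Closed-form anchors used in tests: ANI(J=1) = 100;
ANI(J=0.5, k=31) = 100·(1 + ln(2/3)/31) ≈ 98.692; QV at completeness 0.9
and k=31 is ≈ 24.69.

Hierarchical clustering uses average linkage (UPGMA) on 1 − J (shared
counts are converted to Jaccard first, so ordering is scale-free) or
(100 − ANI)/100. Directional QV is not a metric and is refused.

## Genome anchoring and conservation

Anchoring projects the index onto one genome's coordinates: for each
0-based start position of each contig, the canonical k-mer of that window
is looked up and the **conservation value** is the fraction of a chosen
genome panel whose column contains it (0 when the k-mer is absent from
the index). The anchor need not be indexed; when it is and the panel
includes it, every non-missing value is ≥ 1/|panel| because a genome
always contains its own k-mers. The value is assigned to the window's
start position — the paper-scale alternative (midpoint, or all covered
positions) only shifts plots by < k bp and cannot change 100-kb bin
means, so the simplest invertible convention was chosen.

Panels are first-class: conservation of a hybrid's contig against its own
species panel versus a donor panel is the introgression scan. Binned
tracks average non-missing values in fixed-width windows (default 100 kb,
configurable; the toy fixtures use 5 kb), and `call_blocks()` labels each
bin by which panel's conservation exceeds the other's by more than a
margin (default 0.1), merging adjacent same-label bins into blocks. This
caller is a deliberate minimal majority rule built on the conservation
statistic — a screening convenience, not a statistical test, and no
significance is attached to block calls.

## The synthetic pangenome generator

`simulate_pangenome()` mutates a uniform-random ancestor independently
per genome (star phylogeny) with per-bp SNPs, geometric-length INDELs,
optional structural variants (deletion, insertion, tandem duplication,
inversion), N-gap runs, and introgression blocks copied from a separately
diverged SNP-only donor lineage. Every event is recorded with
coordinates. One master seed fans out to per-genome substreams so adding
a genome never perturbs existing ones, and a fixed seed reproduces
byte-identical FASTA.

`make_hybrid_fixture()` is the canonical end-to-end input: ancestor →
two founders at 1% SNP divergence (SNP-only so ancestor coordinates stay
aligned and recorded introgression coordinates are exact in the hybrid);
4 + 3 panel members at a further 0.25% SNPs plus 10^-4 indels; and one
hybrid — a panel-A lineage carrying a 40-kb and a 20-kb block from the
panel-B founder on a 200-kb genome, placed at 10-kb-aligned starts, then
diverged 0.25% by SNPs. These rates were chosen once as a toy-scale
caricature of a recent inter-species hybridization in a plant pangenome:
within-panel ANI ≈ 99.5%, cross-panel ≈ 97.4%, and the hybrid
intermediate on both sides, reproducing the qualitative pattern
(own-panel outlier, elevated cross-panel identity, locally inverted
conservation) that motivates the anchored scan.

What the generator does **not** emulate: recombination maps, repeat
families and their copy-number dynamics, sequencing error in reads,
realistic base composition, or phylogenies deeper than a star. Passing
tests therefore demonstrate correctness of the machinery and
recoverability of planted signal under clean conditions — not calibrated
performance on real assemblies.

A useful closed-form sanity law: under per-bp SNP rate p, the expected
fraction of ancestor k-mers destroyed in a genome is 1 − (1−p)^k (≈ 0.268
at p = 0.01, k = 31). The suite checks simulated loss against this within
three standard errors over 20 replicate seeds at 10-kb genomes.

## Numerical and degenerate-input choices

* Jaccard/conservation values are ratios of small integer counts, so
  equality comparisons in run-length merging of bedGraph output are
  exact, not tolerance-based.
* An all-N (or shorter-than-k) genome yields a valid empty column;
  an index with zero k-mers serializes and round-trips.
* Empty track → bedGraph with a header comment only; bins with no valid
  position are missing; the final bin of a contig may be short.
* Clustering refuses matrices with undefined entries rather than
  imputing.
* Tie-breaks in clustering follow `stats::hclust` average linkage, which
  is deterministic for a fixed distance matrix; permuting genome input
  order permutes labels but preserves merge heights.
* Segment width is `4^k %/% n`, computed in 64-bit integer arithmetic;
  the remainder is absorbed by the last segment, so tilings are exact for
  any n ≤ 4^k.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
25 random toy pangenomes of 3–6 genomes × 1–3 kb for oracle equivalence
against an independent string-based brute-force implementation; the
200-kb, 8-genome hybrid fixture for the end-to-end scan; 20 × 10-kb
replicates for the survival law. These sizes keep the full suite under a
minute of compute while exercising every code path at k = 31; the index
machinery itself has no toy-scale assumptions (the compiled scan
processes ~10^6 bases/ms-scale and the format addresses |K| with 64-bit
row counts).

## Known limitations

* Presence/absence only: no k-mer multiplicities, hence no copy-number
  inference in repeats.
* No genotyping layer, and no gene-level or annotation-aware analysis.
* ANI and symmetric-QV formulas are the package's documented choices
  among several in circulation; second-decimal comparisons against other
  tools require confirming they use the same transform.
* The block caller is a margin rule at bin resolution; block boundaries
  are only as sharp as the bin width.
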