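# kmerpan

Reference-free, alignment-free pangenome analysis in R, built on canonical
k-mer presence/absence.

Pangenome studies increasingly start from dozens of whole-genome
assemblies rather than one reference plus reads. Graph-based pangenomes
capture this variation but need expensive multiple alignment and struggle
with large, repeat-rich plant and animal genomes. kmerpan takes the k-mer
decomposition route instead: a set *G* of genomes is reduced to the set
*K* of all observed **canonical k-mers** (a k-mer and its reverse
complement count as one, represented by the lexicographically smaller),
and the pangenome is the |K| × |G| binary table *X* of presence/absence
values. Any variant that adds or removes a k-mer — SNP, INDEL, or SV —
is encoded, no reference or annotation is required, and chromosome-level
assemblies, contig sets and unaligned reads can be indexed side by side.

It is intended for researchers who want whole-genome relatedness
statistics and locus-level core/variable analysis across many genomes of
one or several related species, without committing to a reference
coordinate system.

What the package computes:

* **k-mer index** — canonical 2-bit-encoded k-mers (default k = 31,
  stored as exact 64-bit codes) with bit-packed per-genome presence;
  built in memory-bounded rounds over segments of the theoretical code
  space, bit-identical for every segmentation; versioned binary `.pki`
  on-disk format with lossless round-trip.
* **Adjacency statistics** — shared k-mer counts |K_i ∩ K_j| by bitwise
  column intersection, and conversions to Jaccard J = |K_i∩K_j|/|K_i∪K_j|,
  ANI via the Mash transform ANI% = 100·(1 + ln(2J/(1+J))/k), and
  MerQury-style QV = −10·log10(1 − c^(1/k)) with completeness
  c = |K_i∩K_j|/|K_i| (or a symmetric union-denominator variant). UPGMA
  clustering and ggplot2 heatmaps.
* **Genome anchoring** — per-position *k-mer conservation* along any
  anchor genome: the fraction of a chosen genome panel containing the
  canonical k-mer at each position; fixed-width binning, bedGraph/BED/TSV
  export, and a two-panel margin rule that calls candidate introgression
  blocks.
* **Synthetic pangenomes** — a seeded generator (star phylogeny with
  SNPs, INDELs, SVs, N-gaps, donor introgressions, full ground truth)
  and a standard two-panel + hybrid fixture, so every claim above is
  testable without downloads.

## Worked example: finding a hybrid and its introgressions

The built-in fixture mimics a recent hybridization between two diverged
species panels: 4 + 3 genomes plus one hybrid (`H01`) carrying a 40-kb
and a 20-kb donor block on a 200-kb genome.

```r
library(kmerpan)

fx  <- make_hybrid_fixture(seed = 1)
idx <- build_index(fx$sequences[fx$genomes$genome_id], k = 31)
glance(idx)
#> # A tibble: 1 × 3
#>       k n_genomes n_kmers
#>   <int>     <int>   <dbl>
#> 1    31         8  415041

ani <- to_ani(to_jaccard(shared_kmer_matrix(idx)))
round(ani$values[c("A01", "A02", "H01", "B01"), c("A01", "A02", "H01", "B01")], 2)
#>        A01    A02    H01    B01
#> A01 100.00  99.49  99.02  97.44
#> A02  99.49 100.00  99.00  97.43
#> H01  99.02  99.00 100.00  98.16
#> B01  97.44  97.43  98.16 100.00
```

Ordinary panel-A members sit near 99.5% ANI with each other and 97.4%
with panel B. `H01` is the outlier on both sides — only ~99.0% within
its own panel but an elevated 98.2% across panels — the classic
signature of a hybrid. Anchoring the index on `H01` localizes why:

```r
tr_a <- anchor_conservation(idx, c(chr = fx$sequences$H01), subset = fx$panel_a)
tr_b <- anchor_conservation(idx, c(chr = fx$sequences$H01), subset = fx$panel_b)
call_blocks(bin_track(tr_a, 5000), bin_track(tr_b, 5000), margin = 0.1)
#> # A tibble: 5 × 5
#>   contig  start    end label n_bins
#>   <chr>   <int>  <int> <chr>  <int>
#> 1 chr         0  50000 A         10
#> 2 chr     50000  90000 B          8
#> 3 chr     90000 140000 A         10
#> 4 chr    140000 160000 B          4
#> 5 chr    160000 200000 A          8
```

The two donor-labeled (`B`) blocks coincide exactly with the planted
introgressions at [50000, 90000) and [140000, 160000): inside them the
hybrid's k-mers are shared with the donor panel but not its own.
`autoplot()` on the adjacency matrix or on a binned track draws the
corresponding heatmap and conservation profile, and `write_track()` /
`write_matrix_tsv()` export bedGraph/BED/TSV with provenance headers.

The same analysis from a shell:

```sh
kmerpan fixture --preset hybrid --seed 1 -o fx/
kmerpan index -k 31 -o pan.pki fx/*.fa
kmerpan adjacency -i pan.pki -o ani.tsv --stat ani --cluster --heatmap ani.png
kmerpan anchor -i pan.pki --anchor fx/H01.fa --subset panelA.txt --bin 5000 -o a.tsv
kmerpan anchor -i pan.pki --anchor fx/H01.fa --subset panelB.txt --bin 5000 -o b.tsv
kmerpan blocks --a a.tsv --b b.tsv --margin 0.1 -o blocks.bed
```

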