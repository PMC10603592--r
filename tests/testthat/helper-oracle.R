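# Independent brute-force oracle: plain string windows, string reverse
# complement, lexicographic min. Shares no code with the compiled 2-bit
# rolling scanner it is used to check.

o_revcomp <- function(s) chartr("ACGT", "TGCA", stringi::stri_reverse(s))

o_windows <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

# canonical k-mers of valid windows, with 0-based start positions
o_scan <- function(seq, k) {
  w <- o_windows(seq, k)
  ok <- grepl("^[ACGT]+$", w)
  canon <- pmin(w[ok], o_revcomp(w[ok]))
  list(pos = which(ok) - 1L, kmer = canon)
}

# distinct canonical k-mer set of a genome (one or more contig strings)
o_kmer_set <- function(contigs, k) {
  unique(unlist(lapply(contigs, function(s) o_scan(s, k)$kmer),
                use.names = FALSE))
}

o_shared <- function(set_a, set_b) length(intersect(set_a, set_b))

o_jaccard <- function(set_a, set_b) {
  s <- o_shared(set_a, set_b)
  s / (length(set_a) + length(set_b) - s)
}

# per-position conservation of anchor_seq against a list of genome k-mer sets
o_conservation <- function(anchor_seq, k, genome_sets) {
  L <- nchar(anchor_seq)
  n <- max(L - k + 1, 0)
  out <- rep(NA_real_, n)
  sc <- o_scan(anchor_seq, k)
  if (length(sc$pos)) {
    hits <- vapply(sc$kmer, function(km)
      sum(vapply(genome_sets, function(set) km %in% set, logical(1))),
      numeric(1))
    out[sc$pos + 1L] <- hits / length(genome_sets)
  }
  out
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

# a small random pangenome (named list of sequences) via the generator
random_toy_pangenome <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  L <- sample(1000:3000, 1)
  sim <- simulate_pangenome(
    n_genomes = n, genome_length = L, seed = seed,
    snp_rate = stats::runif(1, 0.001, 0.02),
    indel_rate = stats::runif(1, 0, 0.002), indel_mean = 3,
    n_gap_rate = stats::runif(1, 0, 0.003)
  )
  sim$sequences[sim$genomes$genome_id]
}
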