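test_that("sub-index construction matches hand decomposition and segment filters", {
  # ACGTACGT -> windows ACG,CGT,GTA,TAC,ACG,CGT canonicalize to {ACG, GTA}
  sub <- build_subindex(list(g1 = "ACGTACGT"), k = 3)
  expect_equal(kmerpan:::.kc_rows_to_double(sub$codes),
               kmer_encode(c("ACG", "GTA")))
  expect_equal(sub$per_genome_counts, 2)

  # a segment covering only codes <= encode("ACG") keeps ACG, drops GTA
  segs <- kmer_segments(3, 8)  # width 8: ACG=6 in segment 0, GTA=44 in 5
  sub0 <- build_subindex(list(g1 = "ACGTACGT"), k = 3, ordinal = 0,
                         n_segments = 8)
  expect_equal(kmerpan:::.kc_rows_to_double(sub0$codes), kmer_encode("ACG"))

  # all-N genome gives an empty sub-index
  subN <- build_subindex(list(g1 = strrep("N", 50)), k = 3)
  expect_equal(subN$n_kmers, 0)
})

test_that("merging sub-indexes is an order-independent exact tiling operation", {
  set.seed(42)
  genomes <- list(g1 = random_seq(500), g2 = random_seq(500))

  one <- merge_subindexes(list(build_subindex(genomes, k = 7)))
  parts <- lapply(0:7, function(o) build_subindex(genomes, k = 7, ordinal = o,
                                                  n_segments = 8))
  eight <- merge_subindexes(parts)
  expect_identical(eight, one)

  # shuffled part order changes nothing
  expect_identical(merge_subindexes(parts[c(5, 1, 8, 3, 2, 7, 4, 6)]), one)

  # overlapping segments and mismatched genome sets are rejected
  expect_error(merge_subindexes(list(parts[[1]], parts[[1]])), "overlap")
  other <- build_subindex(list(gX = "ACGTACGT"), k = 7)
  expect_error(merge_subindexes(list(parts[[1]], other)), "genome sets|tilings")
})

test_that("build_index equals brute-force per-genome k-mer sets", {
  for (seed in c(2, 9)) {
    genomes <- random_toy_pangenome(seed)
    idx <- build_index(genomes, k = 31)
    for (g in names(genomes)) {
      expect_setequal(index_kmers(idx, g), o_kmer_set(genomes[[g]], 31))
    }
    # rows all canonical and strictly ascending; every row has a set bit
    km <- index_kmers(idx)
    expect_equal(km, pmin(km, o_revcomp(km)))
    pres <- sapply(names(genomes), function(g) index_presence(idx, g))
    expect_true(all(rowSums(pres) >= 1))
    expect_equal(unname(idx$per_genome_counts), unname(colSums(pres)))
  }
})

test_that("identical genomes share all columns; disjoint genomes share none", {
  set.seed(5)
  s <- random_seq(800)
  idx <- build_index(list(a = s, b = s, c = s), k = 21)
  expect_equal(idx$n_kmers, length(o_kmer_set(s, 21)))
  expect_identical(index_presence(idx, "a"), index_presence(idx, "b"))
  expect_identical(index_presence(idx, "a"), index_presence(idx, "c"))

  # two random 31-mer repertoires have no chance collisions at this scale
  g1 <- random_seq(1000); g2 <- random_seq(1000)
  expect_equal(o_shared(o_kmer_set(g1, 31), o_kmer_set(g2, 31)), 0)
  idx2 <- build_index(list(g1 = g1, g2 = g2), k = 31)
  pres <- cbind(index_presence(idx2, "g1"), index_presence(idx2, "g2"))
  expect_true(all(rowSums(pres) == 1))
})

test_that("splitting a genome into contigs loses only junction-spanning k-mers", {
  set.seed(13)
  k <- 21L
  s <- random_seq(2000)
  cuts <- c(0, 400, 900, 1300, 1700, 2000)
  pieces <- substring(s, head(cuts, -1) + 1, tail(cuts, -1))
  whole <- build_index(list(g = s), k = k)
  split <- build_index(list(g = setNames(pieces, paste0("c", 1:5))), k = k)
  kw <- index_kmers(whole, "g")
  ks <- index_kmers(split, "g")
  expect_true(all(ks %in% kw))             # splitting never adds k-mers
  expect_lte(length(setdiff(kw, ks)), 4 * (k - 1))
})

test_that("the k-mer set grows monotonically with added genomes", {
  set.seed(17)
  g1 <- random_seq(600); g2 <- random_seq(600); g3 <- random_seq(600)
  k12 <- index_kmers(build_index(list(g1 = g1, g2 = g2), k = 15))
  k123 <- index_kmers(build_index(list(g1 = g1, g2 = g2, g3 = g3), k = 15))
  expect_true(all(k12 %in% k123))
})

test_that("duplicate genome ids are rejected before any scan", {
  expect_error(build_index(list(a = "ACGTACGT", a = "ACGTACGT"), k = 3),
               "duplicate genome_id")
})

test_that("indexes read genomes from FASTA files with ids from file stems", {
  d <- withr::local_tempdir()
  set.seed(21)
  s1 <- random_seq(300); s2 <- random_seq(300)
  write_fasta(c(chr1 = s1), file.path(d, "alpha.fa"))
  write_fasta(c(chr1 = s2), file.path(d, "beta.fa.gz"))
  idx <- build_index(file.path(d, c("alpha.fa", "beta.fa.gz")), k = 11)
  expect_equal(idx$genome_ids, c("alpha", "beta"))
  expect_identical(idx, build_index(list(alpha = c(chr1 = s1),
                                         beta = c(chr1 = s2)), k = 11))
})
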