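test_that("shared counts are exact set intersections of column k-mer sets", {
  # Ki = {ACG, GTA} (codes 6, 44), Kj = {ACG} -> shared 1
  idx <- build_index(list(gi = "ACGTACGT", gj = "ACG"), k = 3)
  sh <- shared_kmer_matrix(idx)
  expect_equal(sh$values["gi", "gj"], 1)
  expect_equal(sh$values["gi", "gi"], 2)  # diagonal = per-genome counts
  expect_equal(sh$values["gj", "gj"], 1)

  # identical columns: |K| everywhere; disjoint columns: 0 off-diagonal
  set.seed(31)
  s <- random_seq(400)
  ident <- shared_kmer_matrix(build_index(list(a = s, b = s), k = 21))
  expect_true(all(ident$values == ident$values[1, 1]))
  disj <- shared_kmer_matrix(build_index(list(a = random_seq(400),
                                              b = random_seq(400)), k = 31))
  expect_equal(disj$values["a", "b"], 0)
})

test_that("pairwise statistics agree with the brute-force oracle on toys", {
  for (seed in c(4, 8)) {
    genomes <- random_toy_pangenome(seed)
    idx <- build_index(genomes, k = 31)
    sh <- shared_kmer_matrix(idx)
    J <- to_jaccard(sh)
    sets <- lapply(genomes, o_kmer_set, k = 31)
    for (a in names(genomes)) for (b in names(genomes)) {
      expect_equal(sh$values[a, b], o_shared(sets[[a]], sets[[b]]))
      expect_equal(J$values[a, b], o_jaccard(sets[[a]], sets[[b]]))
    }
    expect_true(isSymmetric(sh$values))
    expect_true(isSymmetric(J$values))
    expect_equal(unname(diag(J$values)), rep(1, length(genomes)))
  }
})

test_that("Jaccard handles the empty-genome case as missing, not zero", {
  idx <- build_index(list(a = "ACGTACGT", empty = strrep("N", 30)), k = 3)
  J <- to_jaccard(shared_kmer_matrix(idx))
  expect_true(is.na(J$values["a", "empty"]))
  expect_true(is.na(J$values["empty", "empty"]))
  expect_equal(J$values["a", "a"], 1)
})

test_that("the Mash ANI transform matches its closed form and is monotone", {
  idx <- build_index(list(a = "ACGTACGT", b = "ACGTACGT"), k = 3)
  J <- to_jaccard(shared_kmer_matrix(idx))
  expect_equal(to_ani(J)$values["a", "b"], 100)  # J = 1

  # closed form at J = 0.5, k = 31
  J2 <- J; J2$values[] <- 0.5; diag(J2$values) <- 1
  ani <- to_ani(J2, k = 31)
  expect_equal(ani$values["a", "b"], 100 * (1 + log(2 / 3) / 31))
  expect_equal(ani$values["a", "b"], 98.692, tolerance = 0.001 / 98)

  # strictly increasing in J at fixed k
  J3 <- J; J3$values[] <- 0.6; diag(J3$values) <- 1
  expect_gt(to_ani(J3, k = 31)$values["a", "b"], ani$values["a", "b"])

  # J = 0 undefined; tiny J clamped at 0 rather than negative
  J4 <- J; J4$values["a", "b"] <- J4$values["b", "a"] <- 0
  expect_true(is.na(to_ani(J4, k = 31)$values["a", "b"]))
})

test_that("ANI and Jaccard rank genome pairs identically", {
  set.seed(6)
  genomes <- random_toy_pangenome(10)
  J <- to_jaccard(shared_kmer_matrix(build_index(genomes, k = 31)))
  ani <- to_ani(J)
  lw <- lower.tri(J$values)
  expect_equal(order(J$values[lw]), order(ani$values[lw]))
})

test_that("QV follows the MerQury formula with a documented cap", {
  set.seed(44)
  s <- random_seq(300)
  idx <- build_index(list(a = s, b = s), k = 21)
  qv <- to_qv(shared_kmer_matrix(idx))
  expect_equal(qv$values["a", "b"], 99)  # all of a's k-mers in b: E = 0, cap

  # shared fraction 0.9 at k = 31
  sh <- shared_kmer_matrix(build_index(list(a = s, b = s), k = 31))
  sh$per_genome_counts[] <- 10
  sh$values[] <- 9; diag(sh$values) <- 10
  qv2 <- to_qv(sh)
  expect_equal(qv2$values["a", "b"], -10 * log10(1 - 0.9^(1 / 31)))
  expect_equal(qv2$values["a", "b"], 24.69, tolerance = 0.01 / 24)

  # zero sharing: E = 1, QV = 0
  sh$values["a", "b"] <- sh$values["b", "a"] <- 0
  expect_equal(to_qv(sh)$values["a", "b"], 0)

  # symmetric variant is symmetric and equals directional for identical sets
  idx3 <- build_index(list(a = s, b = s, c = random_seq(300)), k = 21)
  qs <- to_qv(shared_kmer_matrix(idx3), symmetric = TRUE)
  expect_true(isSymmetric(qs$values))
  qd <- to_qv(shared_kmer_matrix(idx3), symmetric = FALSE)
  expect_equal(qs$values["a", "b"], qd$values["a", "b"])  # identical sets
})

test_that("clustering puts identical genomes on adjacent leaves, topology stable", {
  set.seed(51)
  s <- random_seq(1000); far <- random_seq(1000)
  # G0 == G1, G2 distant: with shared background so Jaccard is defined
  base <- random_seq(1000)
  g0 <- paste0(base, s); g1 <- paste0(base, s); g2 <- paste0(base, far)
  idx <- build_index(list(G0 = g0, G1 = g1, G2 = g2), k = 21)
  cl <- cluster_genomes(to_jaccard(shared_kmer_matrix(idx)))
  pos <- match(c("G0", "G1"), cl$order)
  expect_equal(abs(diff(pos)), 1)  # adjacent leaves

  # |G| = 2: leaf order is input order
  idx2 <- build_index(list(x = g0, y = g2), k = 21)
  expect_equal(cluster_genomes(to_jaccard(shared_kmer_matrix(idx2)))$order,
               c("x", "y"))

  # permuting genome input order preserves merge heights (tree topology)
  idxp <- build_index(list(G2 = g2, G0 = g0, G1 = g1), k = 21)
  h1 <- sort(cluster_genomes(to_jaccard(shared_kmer_matrix(idx)))$hclust$height)
  h2 <- sort(cluster_genomes(to_jaccard(shared_kmer_matrix(idxp)))$hclust$height)
  expect_equal(h1, h2)

  expect_error(cluster_genomes(to_jaccard(shared_kmer_matrix(
    build_index(list(only = g0), k = 21)))), "at least 2")
})

test_that("matrix TSV has genome ids on both margins and NA for undefined", {
  idx <- build_index(list(a = "ACGTACGT", empty = strrep("N", 30)), k = 3)
  J <- to_jaccard(shared_kmer_matrix(idx))
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(J, p, provenance = "test run")
  lines <- readLines(p)
  expect_equal(lines[1], "# test run")
  expect_equal(strsplit(lines[2], "\t")[[1]], c("genome_id", "a", "empty"))
  row_a <- strsplit(lines[3], "\t")[[1]]
  expect_equal(row_a, c("a", "1.0000", "NA"))
})

test_that("tidy and autoplot expose the adjacency matrix in long form", {
  set.seed(60)
  s <- random_seq(500)
  idx <- build_index(list(a = s, b = s, c = random_seq(500)), k = 21)
  adj <- to_jaccard(shared_kmer_matrix(idx))
  td <- tidy(adj)
  expect_equal(nrow(td), 9)
  expect_equal(td$value[td$genome_1 == "a" & td$genome_2 == "b"],
               adj$values["a", "b"])
  gg <- autoplot(adj)
  expect_s3_class(gg, "ggplot")
})
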