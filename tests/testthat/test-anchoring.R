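test_that("conservation is 1 everywhere when all genomes are identical", {
  set.seed(70)
  s <- random_seq(600)
  idx <- build_index(list(a = s, b = s, c = s), k = 21)
  tr <- anchor_conservation(idx, c(chr = s), anchor_id = "a")
  expect_equal(nrow(tr), 600 - 21 + 1)
  expect_true(all(tr$value == 1))
})

test_that("a private insertion shows 1/|G| conservation, 0 against the others", {
  set.seed(71)
  k <- 21L
  base <- random_seq(2000)
  ins <- random_seq(500)
  anchor <- paste0(substr(base, 1, 1000), ins, substr(base, 1001, 2000))
  genomes <- list(anc = anchor, o1 = base, o2 = base)
  idx <- build_index(genomes, k = k)

  tr_all <- anchor_conservation(idx, c(chr = anchor), anchor_id = "anc")
  inside <- tr_all$pos >= 1000 + 0 & tr_all$pos <= 1500 - k  # windows fully in the insertion
  expect_true(all(tr_all$value[inside] == 1 / 3))

  tr_sub <- anchor_conservation(idx, c(chr = anchor), subset = c("o1", "o2"))
  expect_true(all(tr_sub$value[inside] == 0))

  # full-track agreement with the brute-force oracle, both denominators
  sets <- lapply(genomes, o_kmer_set, k = k)
  expect_equal(tr_all$value, o_conservation(anchor, k, sets))
  expect_equal(tr_sub$value, o_conservation(anchor, k, sets[c("o1", "o2")]))
})

test_that("an indexed anchor always contains its own k-mers", {
  genomes <- random_toy_pangenome(14)
  idx <- build_index(genomes, k = 31)
  g1 <- names(genomes)[1]
  tr <- anchor_conservation(idx, c(chr = genomes[[1]]), anchor_id = g1)
  ok <- !is.na(tr$value)
  expect_true(all(tr$value[ok] >= 1 / length(genomes)))
  # missing exactly at windows containing non-ACGT bases
  sc <- o_scan(genomes[[g1]][1], 31)
  expect_equal(which(!is.na(tr$value)) - 1L, sc$pos)
})

test_that("unknown subset ids are listed in the error", {
  idx <- build_index(list(a = "ACGTACGTACGT"), k = 3)
  expect_error(anchor_conservation(idx, c(chr = "ACGT"), subset = c("a", "zz")),
               "zz")
})

test_that("binning averages non-missing positions per fixed-width bin", {
  k <- 3L
  # constant 0.8 over 250 positions (L = 252), bins of 100
  tr <- kmerpan:::new_track(
    tibble::tibble(contig = "c", pos = 0:249, value = 0.8),
    "anc", k, "a", c(c = 252L))
  bins <- bin_track(tr, 100)
  expect_equal(bins$mean_conservation, c(0.8, 0.8, 0.8))
  expect_equal(bins$n_valid, c(100L, 100L, 50L))
  expect_equal(bins$bin_end, c(100L, 200L, 252L))

  # mixed track [1, 1, 0, NA] with bin width 2
  tr2 <- kmerpan:::new_track(
    tibble::tibble(contig = "c", pos = 0:3, value = c(1, 1, 0, NA)),
    "anc", k, "a", c(c = 6L))
  b2 <- bin_track(tr2, 2)
  expect_equal(b2$mean_conservation[1:2], c(1, 0))
  expect_equal(b2$n_valid[1:2], c(2L, 1L))
  expect_true(is.na(b2$mean_conservation[3]))  # tail bin beyond last window

  # all-missing track: all bins missing
  tr3 <- kmerpan:::new_track(
    tibble::tibble(contig = "c", pos = 0:9, value = NA_real_),
    "anc", k, "a", c(c = 12L))
  expect_true(all(is.na(bin_track(tr3, 5)$mean_conservation)))
})

test_that("binning is consistent with the whole-contig mean when bins are full", {
  set.seed(75)
  genomes <- list(a = random_seq(1200), b = random_seq(1200))
  genomes$b <- paste0(substr(genomes$a, 1, 600), substr(genomes$b, 1, 600))
  idx <- build_index(genomes, k = 11)
  tr <- anchor_conservation(idx, c(chr = genomes$a))
  # one bin covering everything equals the plain mean
  bins <- bin_track(tr, 2000)
  expect_equal(bins$mean_conservation, mean(tr$value, na.rm = TRUE))
  # weighted mean of full bins reproduces the whole-track mean
  b100 <- bin_track(tr, 100)
  expect_equal(sum(b100$mean_conservation * b100$n_valid, na.rm = TRUE) /
                 sum(b100$n_valid),
               mean(tr$value, na.rm = TRUE))
})

test_that("bedGraph output run-length merges and omits missing spans", {
  tr <- kmerpan:::new_track(
    tibble::tibble(contig = "c", pos = 0:2, value = c(0.5, 0.5, 1.0)),
    "anc", 3L, "a", c(c = 5L))
  p <- tempfile(fileext = ".bedGraph")
  write_track(tr, p)
  lines <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_equal(lines, c("c\t0\t2\t0.5", "c\t2\t3\t1"))

  # missing positions break runs and are omitted
  tr2 <- kmerpan:::new_track(
    tibble::tibble(contig = "c", pos = 0:4, value = c(0.5, NA, 0.5, 0.5, NA)),
    "anc", 3L, "a", c(c = 7L))
  write_track(tr2, p)
  lines2 <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_equal(lines2, c("c\t0\t1\t0.5", "c\t2\t4\t0.5"))

  # empty track: header comment only
  tr0 <- kmerpan:::new_track(
    tibble::tibble(contig = character(0), pos = integer(0), value = numeric(0)),
    "anc", 3L, "a", c(c = 2L))
  write_track(tr0, p)
  expect_true(all(grepl("^#", readLines(p))))

  # binned output as BED4 keeps bin boundaries
  bins <- bin_track(tr, 2)
  write_track(bins, p, format = "BED")
  bl <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_equal(length(bl), sum(!is.na(bins$mean_conservation)))
  expect_equal(strsplit(bl[1], "\t")[[1]][1:3], c("c", "0", "2"))
})

test_that("block calling labels bins by panel margin and merges runs", {
  mk_bins <- function(vals, width = 10L) {
    n <- length(vals)
    structure(tibble::tibble(contig = "c",
                             bin_start = as.integer((0:(n - 1)) * width),
                             bin_end = as.integer((1:n) * width),
                             mean_conservation = vals,
                             n_valid = rep(width, n)),
              class = c("binned_track", class(tibble::tibble())))
  }
  a <- mk_bins(c(0.9, 0.9, 0.3, 0.3, 0.9))
  b <- mk_bins(c(0.4, 0.4, 0.8, 0.8, 0.4))
  blocks <- call_blocks(a, b, margin = 0.1)
  expect_equal(blocks$label, c("A", "B", "A"))
  expect_equal(blocks$start, c(0L, 20L, 40L))
  expect_equal(blocks$end, c(20L, 40L, 50L))
  expect_equal(blocks$n_bins, c(2L, 2L, 1L))

  # identical panels: everything ambiguous
  expect_equal(unique(call_blocks(a, a, margin = 0.1)$label), "ambiguous")

  # margin 0 with panel A strictly higher everywhere: one A block
  hi <- mk_bins(rep(0.9, 5)); lo <- mk_bins(rep(0.5, 5))
  blk <- call_blocks(hi, lo, margin = 0)
  expect_equal(nrow(blk), 1)
  expect_equal(blk$label, "A")
  expect_equal(c(blk$start, blk$end), c(0L, 50L))

  # mismatched bin grids are an error
  expect_error(call_blocks(a, mk_bins(c(0.4, 0.4), width = 10L)), "grid")
})
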