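# On-disk index format ".pki" (see inst/doc-format: docs/ in README):
#   bytes 0-3   magic "KPAN"
#   bytes 4-7   format version, int32 little-endian (currently 1)
#   bytes 8-11  metadata length M, int32 little-endian
#   M bytes     JSON metadata: k, genome_ids, contig table, n_kmers,
#               per_genome_counts
#   8*|K| bytes sorted canonical codes, unsigned 64-bit little-endian
#   |K|*ceiling(|G|/8) bytes bit-packed presence rows (genome g of a row at
#               byte g %/% 8, bit g %% 8)
# Total file length is fully determined by the metadata, which is how
# truncation is detected.

PKI_MAGIC <- charToRaw("KPAN")
PKI_VERSION <- 1L

#' Write a k-mer index to disk
#'
#' Serialises a [kmer_index] to the package's versioned `.pki` binary
#' format: magic bytes, format version, a JSON metadata block (k, genome
#' ids in column order, contig table, counts), the sorted 64-bit
#' little-endian code array, and the bit-packed presence block. The
#' round-trip `read_index(write_index(x, p))` is bit-identical to `x`.
#'
#' @param index A [kmer_index].
#' @param path Output path (conventionally `.pki`).
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  meta <- list(
    k = index$k,
    genome_ids = index$genome_ids,
    contig_genome = index$contigs$genome_id,
    contig_name = index$contigs$contig,
    contig_length = index$contigs$length,
    n_kmers = index$n_kmers,
    per_genome_counts = unname(index$per_genome_counts)
  )
  mraw <- charToRaw(as.character(jsonlite::toJSON(meta, auto_unbox = FALSE,
                                                  digits = NA)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(PKI_MAGIC, con)
  writeBin(PKI_VERSION, con, size = 4L, endian = "little")
  writeBin(length(mraw), con, size = 4L, endian = "little")
  writeBin(mraw, con)
  writeBin(index$codes, con)
  writeBin(index$presence, con)
  invisible(path)
}

read_index_meta <- function(con, path) {
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4 || !identical(magic, PKI_MAGIC))
    stop("'", path, "' is not a kmerpan index (bad magic bytes)",
         call. = FALSE)
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(version) != 1 || version != PKI_VERSION)
    stop("'", path, "' has incompatible index format version ",
         if (length(version)) version else "<missing>",
         " (this build reads version ", PKI_VERSION, ")", call. = FALSE)
  mlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  mraw <- readBin(con, "raw", n = mlen)
  if (length(mraw) < mlen)
    stop("'", path, "' is truncated inside the metadata block", call. = FALSE)
  jsonlite::fromJSON(rawToChar(mraw), simplifyVector = TRUE)
}

#' Read a k-mer index from disk
#'
#' @param path Path to a `.pki` file written by [write_index()].
#' @return A [kmer_index].
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  meta <- read_index_meta(con, path)
  n_kmers <- as.numeric(meta$n_kmers)
  n_genomes <- length(meta$genome_ids)
  row_bytes <- (n_genomes + 7) %/% 8
  codes <- readBin(con, "raw", n = 8 * n_kmers)
  presence <- readBin(con, "raw", n = n_kmers * row_bytes)
  if (length(codes) < 8 * n_kmers || length(presence) < n_kmers * row_bytes)
    stop("'", path, "' is truncated: payload shorter than metadata declares",
         call. = FALSE)
  if (length(readBin(con, "raw", n = 1L)) != 0)
    stop("'", path, "' has trailing bytes after the declared payload",
         call. = FALSE)
  new_kmer_index(
    k = meta$k,
    genome_ids = as.character(meta$genome_ids),
    contigs = tibble::tibble(
      genome_id = as.character(unlist(meta$contig_genome)),
      contig = as.character(unlist(meta$contig_name)),
      length = as.integer(unlist(meta$contig_length))
    ),
    codes = codes,
    presence = presence,
    per_genome_counts = as.numeric(meta$per_genome_counts)
  )
}

#' Read only the metadata of an on-disk index
#'
#' @param path Path to a `.pki` file.
#' @return A list with `k`, `genome_ids`, `n_kmers`, `per_genome_counts`
#'   and the contig table.
#' @export
index_info <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  meta <- read_index_meta(con, path)
  list(
    k = as.integer(meta$k),
    genome_ids = as.character(meta$genome_ids),
    n_kmers = as.numeric(meta$n_kmers),
    per_genome_counts = setNames(as.numeric(meta$per_genome_counts),
                                 as.character(meta$genome_ids)),
    contigs = tibble::tibble(
      genome_id = as.character(unlist(meta$contig_genome)),
      contig = as.character(unlist(meta$contig_name)),
      length = as.integer(unlist(meta$contig_length))
    )
  )
}
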