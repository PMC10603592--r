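#' @title The k-mer presence/absence index
#' @description
#' A `kmer_index` is the pangenome representation at the heart of the
#' package: the set K of all canonical k-mers observed in at least one input
#' genome, together with a |K| x |G| binary table recording which genomes
#' contain each k-mer. It is reference-free (no coordinate system) and
#' robust to input contiguity — chromosome-level assemblies, contig sets and
#' unaligned reads index identically up to junction-spanning k-mers.
#'
#' Internals: `codes` is a raw vector of |K| little-endian 8-byte canonical
#' codes in strictly ascending order; `presence` packs each k-mer row into
#' `ceiling(|G|/8)` bytes, genome g at byte `g %/% 8`, bit `g %% 8`. Column
#' order is the order genomes were supplied, recorded in `genome_ids`.
#' @name kmer_index
NULL

new_kmer_index <- function(k, genome_ids, contigs, codes, presence,
                           per_genome_counts) {
  structure(
    list(
      k = as.integer(k),
      genome_ids = as.character(genome_ids),
      contigs = tibble::tibble(
        genome_id = as.character(contigs$genome_id),
        contig = as.character(contigs$contig),
        length = as.integer(contigs$length)
      ),
      codes = codes,
      presence = presence,
      n_kmers = as.numeric(length(codes) / 8),
      per_genome_counts = setNames(as.numeric(per_genome_counts),
                                   as.character(genome_ids))
    ),
    class = "kmer_index"
  )
}

contig_table <- function(gs) {
  tibble::tibble(
    genome_id = rep(purrr::map_chr(gs, "genome_id"),
                    purrr::map_int(gs, ~ length(.x$contigs))),
    contig = unlist(purrr::map(gs, ~ names(.x$contigs)), use.names = FALSE) %||% character(0),
    length = unlist(purrr::map(gs, ~ unname(nchar(.x$contigs))), use.names = FALSE) %||% integer(0)
  )
}

#' Build a sub-index over one segment of canonical k-mer space
#'
#' Scans all genomes sequentially and records presence/absence of every
#' canonical k-mer falling inside the given segment of the theoretical code
#' space. Sub-indexes over a complete segment tiling concatenate into the
#' full index via [merge_subindexes()]; this is what bounds construction
#' memory by the largest segment's row count.
#'
#' @param genomes Character vector of FASTA/FASTQ paths (names or
#'   `genome_ids` become genome labels; default the file stem) or a named
#'   list of character vectors of contig sequences.
#' @param k Odd k-mer size in \[3, 31\] (default 31).
#' @param ordinal 0-based segment ordinal.
#' @param n_segments Total number of segments in the tiling.
#' @param genome_ids Optional explicit genome labels.
#' @return A `kmer_subindex` object.
#' @export
build_subindex <- function(genomes, k = 31, ordinal = 0, n_segments = 1,
                           genome_ids = NULL) {
  gs <- as_genome_set(genomes, genome_ids)
  build_subindex_gs(gs, k, ordinal, n_segments)
}

build_subindex_gs <- function(gs, k, ordinal, n_segments) {
  res <- .kc_build_subindex(purrr::map(gs, ~ unname(.x$contigs)),
                            as.integer(k), as.integer(ordinal),
                            as.integer(n_segments))
  structure(
    list(
      k = as.integer(k),
      genome_ids = purrr::map_chr(gs, "genome_id"),
      contigs = contig_table(gs),
      segment = list(ordinal = as.integer(ordinal),
                     n_segments = as.integer(n_segments),
                     lo = res$lo, hi = res$hi),
      codes = res$codes,
      presence = res$presence,
      n_kmers = res$n_rows,
      per_genome_counts = as.numeric(res$counts)
    ),
    class = "kmer_subindex"
  )
}

#' Merge sub-indexes into a full k-mer index
#'
#' Sub-indexes must come from one segment tiling (same k, same
#' `n_segments`, same genome set) and cover disjoint segments. The merge is
#' a concatenation in segment order, so the result is independent of the
#' order parts are supplied.
#'
#' @param parts List of `kmer_subindex` objects.
#' @return A [kmer_index] object.
#' @export
merge_subindexes <- function(parts) {
  stopifnot(length(parts) >= 1)
  if (!all(purrr::map_lgl(parts, inherits, "kmer_subindex")))
    stop("parts must be kmer_subindex objects", call. = FALSE)
  k <- parts[[1]]$k
  ids <- parts[[1]]$genome_ids
  nseg <- parts[[1]]$segment$n_segments
  for (p in parts) {
    if (p$k != k) stop("mismatched k across sub-indexes", call. = FALSE)
    if (!identical(p$genome_ids, ids))
      stop("mismatched genome sets across sub-indexes", call. = FALSE)
    if (p$segment$n_segments != nseg)
      stop("sub-indexes come from different segment tilings", call. = FALSE)
  }
  ords <- purrr::map_int(parts, ~ .x$segment$ordinal)
  if (anyDuplicated(ords))
    stop("overlapping segments: ordinal ",
         ords[duplicated(ords)][1], " supplied twice", call. = FALSE)
  parts <- parts[order(ords)]
  codes <- do.call(c, purrr::map(parts, "codes"))
  presence <- do.call(c, purrr::map(parts, "presence"))
  if (!.kc_codes_sorted(codes))
    stop("merged codes are not strictly ascending; sub-indexes overlap",
         call. = FALSE)
  counts <- Reduce(`+`, purrr::map(parts, "per_genome_counts"))
  new_kmer_index(k, ids, parts[[1]]$contigs, codes, presence, counts)
}

#' Build the k-mer presence/absence index of a genome set
#'
#' Decomposes every input genome into canonical k-mers and assembles the
#' |K| x |G| presence/absence table. Construction runs as `n_segments`
#' sequential rounds over equal slices of the theoretical canonical code
#' space, so peak memory scales with the largest segment rather than with
#' |K|; the result is bit-identical for every choice of `n_segments` and
#' `threads`.
#'
#' @inheritParams build_subindex
#' @param n_segments Number of memory-bounding construction rounds
#'   (default 1).
#' @param threads Accepted for interface compatibility; construction is
#'   deterministic and executed as sequential segment rounds regardless.
#' @return A [kmer_index] object.
#' @examples
#' idx <- build_index(list(g1 = "ACGTACGT", g2 = "ACGTTTTT"), k = 3)
#' glance(idx)
#' @export
build_index <- function(genomes, k = 31, n_segments = 1, threads = 1,
                        genome_ids = NULL) {
  stopifnot(n_segments >= 1, threads >= 1)
  gs <- as_genome_set(genomes, genome_ids)  # errors on duplicate ids pre-scan
  parts <- purrr::map(seq_len(n_segments) - 1L,
                      ~ build_subindex_gs(gs, k, .x, n_segments))
  merge_subindexes(parts)
}

#' Canonical k-mers stored in an index
#'
#' @param index A [kmer_index].
#' @param genome Optional genome id; if given, only k-mers present in that
#'   genome are returned.
#' @return Character vector of canonical k-mer strings in ascending code
#'   order.
#' @export
index_kmers <- function(index, genome = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  all_kmers <- .kc_decode_rows(index$codes, index$k)
  if (is.null(genome)) return(all_kmers)
  g <- match(genome, index$genome_ids)
  if (is.na(g)) stop("unknown genome id: ", genome, call. = FALSE)
  all_kmers[.kc_presence_col(index$presence, index$n_kmers,
                             length(index$genome_ids), g - 1L)]
}

#' Presence column of one genome
#'
#' @inheritParams index_kmers
#' @param genome Genome id.
#' @return Logical vector of length |K|.
#' @export
index_presence <- function(index, genome) {
  stopifnot(inherits(index, "kmer_index"))
  g <- match(genome, index$genome_ids)
  if (is.na(g)) stop("unknown genome id: ", genome, call. = FALSE)
  .kc_presence_col(index$presence, index$n_kmers,
                   length(index$genome_ids), g - 1L)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index>\n")
  cat("  k        :", x$k, "\n")
  cat("  genomes  :", length(x$genome_ids), paste0("(", paste(head(x$genome_ids, 6),
      collapse = ", "), if (length(x$genome_ids) > 6) ", ..." else "", ")"), "\n")
  cat("  k-mers   :", format(x$n_kmers, big.mark = ","), "\n")
  invisible(x)
}

#' Tidy a k-mer index into a per-genome summary
#'
#' @param x A [kmer_index].
#' @param ... Unused.
#' @return A tibble with one row per genome: `genome_id`, `n_kmers`
#'   (distinct canonical k-mers in that genome) and `n_contigs`.
#' @export
tidy.kmer_index <- function(x, ...) {
  nc <- dplyr::count(x$contigs, .data$genome_id, name = "n_contigs")
  tibble::tibble(genome_id = x$genome_ids,
                 n_kmers = unname(x$per_genome_counts)) |>
    dplyr::left_join(nc, by = "genome_id")
}

#' One-row summary of a k-mer index
#'
#' @param x A [kmer_index].
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_genomes`, `n_kmers`.
#' @export
glance.kmer_index <- function(x, ...) {
  tibble::tibble(k = x$k, n_genomes = length(x$genome_ids),
                 n_kmers = x$n_kmers)
}
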