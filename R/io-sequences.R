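#' Read genome sequences from FASTA or FASTQ
#'
#' Accepts FASTA or FASTQ, plain or gzip-compressed; the format is
#' auto-detected from file content (gzip magic bytes, then the first record
#' character), never from the file extension. FASTQ base qualities are
#' discarded — presence/absence indexing needs no counts. Contig order is
#' preserved and contig names are truncated at the first whitespace, the
#' usual convention for assembly FASTA headers.
#'
#' @param path Path to a FASTA/FASTQ file, optionally `.gz`.
#' @return A tibble with columns `contig` (character) and `sequence`
#'   (character, uppercase preserved as read).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- detect_seq_format(path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) {
      stop("malformed ", fmt, " in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) stop("no sequence records in '", path, "'", call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate contig name in '", path, "': ",
         nm[duplicated(nm)][1], call. = FALSE)
  tibble::tibble(contig = nm, sequence = unname(as.character(set)))
}

# Sniff gzip magic then first non-whitespace byte: '>' FASTA, '@' FASTQ.
detect_seq_format <- function(path) {
  head_raw <- readBin(path, "raw", n = 2L)
  if (length(head_raw) == 0) stop("empty file: ", path, call. = FALSE)
  con <- if (length(head_raw) == 2 && head_raw[1] == as.raw(0x1f) &&
             head_raw[2] == as.raw(0x8b)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  first <- rawToChar(readBin(con, "raw", n = 1L))
  while (first %in% c(" ", "\n", "\r", "\t")) {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) stop("empty file: ", path, call. = FALSE)
    first <- rawToChar(b)
  }
  switch(first,
    ">" = "fasta",
    "@" = "fastq",
    stop("'", path, "' is neither FASTA nor FASTQ (first record character '",
         first, "')", call. = FALSE)
  )
}

#' Write genome sequences to FASTA
#'
#' @param sequences Named character vector or a tibble with `contig` and
#'   `sequence` columns, as returned by [read_sequences()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$contig)
  } else if (is.list(sequences)) {
    sequences <- unlist(sequences)
  }
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Normalise the many ways a genome set can be supplied into a uniform list:
#   character vector of paths (names override genome ids; default file stem),
#   or a named list of character vectors of contig sequences.
# Returns list of list(genome_id, contigs = named character vector).
as_genome_set <- function(x, genome_ids = NULL) {
  if (is.character(x)) {
    ids <- genome_ids %||% names(x) %||% file_stem(x)
    if (length(ids) != length(x))
      stop("genome_ids must match the number of input files", call. = FALSE)
    gs <- purrr::map2(x, ids, function(p, id) {
      df <- read_sequences(p)
      list(genome_id = id, contigs = setNames(df$sequence, df$contig))
    })
  } else if (is.list(x)) {
    ids <- genome_ids %||% names(x)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("in-memory genome sets must be named (names become genome ids)",
           call. = FALSE)
    gs <- purrr::map2(x, ids, function(seqs, id) {
      seqs <- unlist(seqs)
      if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        names(seqs) <- paste0("contig", seq_along(seqs))
      list(genome_id = id, contigs = seqs)
    })
  } else {
    stop("genomes must be a character vector of paths or a named list of sequences",
         call. = FALSE)
  }
  ids <- purrr::map_chr(gs, "genome_id")
  if (anyDuplicated(ids))
    stop("duplicate genome_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  unname(gs)
}

file_stem <- function(paths) {
  sub("\\.(fa|fasta|fq|fastq|fna)(\\.gz)?$", "", basename(paths),
      ignore.case = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
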