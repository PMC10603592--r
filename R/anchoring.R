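#' @title Genome anchoring and k-mer conservation
#' @description
#' The index has no coordinate system, but projecting it onto one "anchor"
#' genome recovers spatial context: walking along the anchor, the canonical
#' k-mer starting at each position is looked up in the index and the
#' fraction of a chosen genome panel containing it is recorded. This
#' "k-mer conservation" value is high across core loci shared by most of
#' the pangenome and low across variable loci private to few genomes.
#' Values are assigned to the k-mer's 0-based start position; windows
#' containing a non-ACGT base are missing (`NA`), not zero.
#' @name anchoring
NULL

new_track <- function(df, anchor_id, k, denominator_ids, contig_lengths) {
  structure(df, class = c("conservation_track", class(df)),
            anchor_id = anchor_id, k = as.integer(k),
            denominator_ids = denominator_ids,
            contig_lengths = contig_lengths)
}

#' Per-position k-mer conservation along an anchor genome
#'
#' For every valid k-window of the anchor, the value is the fraction of
#' `subset` genomes whose index column contains that window's canonical
#' k-mer (0 if the k-mer is absent from the index altogether). The anchor
#' need not be one of the indexed genomes; when it is and the subset
#' includes it, every non-missing value is at least 1/|subset|.
#'
#' @param index A [kmer_index].
#' @param anchor Anchor genome: a FASTA/FASTQ path, a named character
#'   vector of contig sequences, or a tibble from [read_sequences()].
#' @param subset Optional character vector of genome ids forming the
#'   denominator panel; defaults to all genomes in the index. Unknown ids
#'   are an error.
#' @param anchor_id Label for the anchor (default: file stem or
#'   `"anchor"`).
#' @return A `conservation_track` tibble with columns `contig`, `pos`
#'   (0-based k-mer start) and `value` (fraction in \[0, 1\] or `NA`),
#'   one row per window position of every contig. Attributes record the
#'   anchor id, k, panel ids and contig lengths.
#' @export
anchor_conservation <- function(index, anchor, subset = NULL,
                                anchor_id = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- as_anchor_seqs(anchor)
  if (is.null(anchor_id))
    anchor_id <- if (is.character(anchor) && length(anchor) == 1 &&
                     file.exists(anchor)) file_stem(anchor) else "anchor"
  subset <- subset %||% index$genome_ids
  unknown <- setdiff(subset, index$genome_ids)
  if (length(unknown))
    stop("subset ids not in index: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cols <- match(subset, index$genome_ids) - 1L
  G <- length(index$genome_ids)
  per_contig <- purrr::imap(seqs, function(s, nm) {
    v <- .kc_anchor_conservation(s, index$k, index$codes, index$presence,
                                 as.integer(cols), G)
    tibble::tibble(contig = nm, pos = seq_along(v) - 1L, value = v)
  })
  df <- dplyr::bind_rows(per_contig)
  if (nrow(df) == 0) df <- tibble::tibble(contig = character(0),
                                          pos = integer(0),
                                          value = numeric(0))
  new_track(df, anchor_id, index$k, subset, setNames(nchar(seqs), names(seqs)))
}

as_anchor_seqs <- function(anchor) {
  if (is.data.frame(anchor)) return(setNames(anchor$sequence, anchor$contig))
  if (is.character(anchor) && length(anchor) == 1 && file.exists(anchor)) {
    df <- read_sequences(anchor)
    return(setNames(df$sequence, df$contig))
  }
  if (is.character(anchor)) {
    if (is.null(names(anchor)))
      names(anchor) <- paste0("contig", seq_along(anchor))
    return(anchor)
  }
  stop("anchor must be a FASTA path, named sequence vector, or tibble",
       call. = FALSE)
}

#' Average conservation in fixed-width bins
#'
#' Bins tile each contig's \[0, length) with `bin_width` windows (the final
#' bin may be short) and average the non-missing per-position values inside
#' each bin. A bin with no valid position is missing. Missing positions are
#' excluded from the mean rather than counted as zero, so N-gaps do not
#' masquerade as variable sequence.
#'
#' @param track A `conservation_track` from [anchor_conservation()].
#' @param bin_width Bin width in bp (default 100000, i.e. 100 kb).
#' @return A `binned_track` tibble: `contig`, `bin_start`, `bin_end`
#'   (0-based half-open), `mean_conservation` (or `NA`) and `n_valid`.
#' @export
bin_track <- function(track, bin_width = 100000) {
  stopifnot(bin_width >= 1)
  lens <- attr(track, "contig_lengths")
  per_contig <- purrr::imap(lens, function(L, nm) {
    starts <- seq(0L, max(L - 1L, 0L), by = bin_width)
    ends <- pmin(starts + bin_width, L)
    sub <- track[track$contig == nm, , drop = FALSE]
    bin_of <- sub$pos %/% bin_width + 1L
    n_valid <- tapply(!is.na(sub$value), factor(bin_of, levels = seq_along(starts)),
                      sum, default = 0L)
    means <- tapply(sub$value, factor(bin_of, levels = seq_along(starts)),
                    function(v) mean(v, na.rm = TRUE), default = NaN)
    means[n_valid == 0] <- NA_real_
    tibble::tibble(contig = nm, bin_start = as.integer(starts),
                   bin_end = as.integer(ends),
                   mean_conservation = as.numeric(means),
                   n_valid = as.integer(n_valid))
  })
  df <- dplyr::bind_rows(per_contig)
  structure(df, class = c("binned_track", class(tibble::tibble())),
            anchor_id = attr(track, "anchor_id"), k = attr(track, "k"),
            denominator_ids = attr(track, "denominator_ids"),
            bin_width = as.integer(bin_width))
}

#' Write a conservation track or binned track to disk
#'
#' bedGraph lines are `contig<TAB>start<TAB>end<TAB>value` with 0-based
#' half-open intervals; adjacent equal values are run-length merged and
#' missing spans are omitted. BED4 writes one line per bin/position with
#' the value in the name column. TSV writes the tibble as-is. Optional
#' provenance comment lines are prepended with `#`.
#'
#' @param x A `conservation_track` or `binned_track`.
#' @param path Output path.
#' @param format One of `"bedGraph"`, `"BED"`, `"TSV"`.
#' @param provenance Character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path, format = c("bedGraph", "BED", "TSV"),
                        provenance = NULL) {
  format <- match.arg(format)
  iv <- track_intervals(x)
  header <- if (length(provenance)) paste0("# ", provenance) else
    "# kmerpan conservation track"
  if (format == "TSV") {
    lines <- c(header,
               paste(colnames(x), collapse = "\t"),
               do.call(paste, c(unname(as.list(as.data.frame(x))), sep = "\t")))
    if (nrow(x) == 0) lines <- c(header, paste(colnames(x), collapse = "\t"))
    writeLines(lines, path)
    return(invisible(path))
  }
  keep <- !is.na(iv$value)
  iv <- iv[keep, , drop = FALSE]
  if (format == "bedGraph") {
    iv <- merge_runs(iv)
    body <- sprintf("%s\t%d\t%d\t%s", iv$contig, iv$start, iv$end,
                    format_num(iv$value))
  } else {
    body <- sprintf("%s\t%d\t%d\t%s", iv$contig, iv$start, iv$end,
                    format_num(iv$value))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

format_num <- function(v) {
  s <- formatC(v, format = "f", digits = 6)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

track_intervals <- function(x) {
  if (inherits(x, "binned_track")) {
    tibble::tibble(contig = x$contig, start = x$bin_start, end = x$bin_end,
                   value = x$mean_conservation)
  } else if (inherits(x, "conservation_track")) {
    tibble::tibble(contig = x$contig, start = x$pos, end = x$pos + 1L,
                   value = x$value)
  } else stop("x must be a conservation_track or binned_track", call. = FALSE)
}

# run-length merge of adjacent intervals with identical values
merge_runs <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  new_run <- c(TRUE, iv$contig[-1] != iv$contig[-nrow(iv)] |
                 iv$start[-1] != iv$end[-nrow(iv)] |
                 iv$value[-1] != iv$value[-nrow(iv)])
  run <- cumsum(new_run)
  tibble::tibble(
    contig = as.character(tapply(iv$contig, run, `[`, 1)),
    start = as.integer(tapply(iv$start, run, min)),
    end = as.integer(tapply(iv$end, run, max)),
    value = as.numeric(tapply(iv$value, run, `[`, 1))
  )
}

#' Label bins by comparing conservation against two genome panels
#'
#' Given binned conservation of the same anchor against two panels A and B
#' (identical bin grids), each bin is labeled `"A"` when its conservation
#' against panel A exceeds panel B by more than `margin`, `"B"` in the
#' opposite case, and `"ambiguous"` otherwise (including bins missing in
#' either track). Adjacent bins with the same label merge into blocks.
#' On a hybrid anchor, `"B"` blocks against (A = own panel, B = donor
#' panel) are candidate introgressions. This caller is a convenience
#' majority rule built on the conservation statistic, not a statistical
#' test.
#'
#' @param bins_a,bins_b `binned_track`s on the same contigs and bin grid.
#' @param margin Minimum conservation difference to call a side (default
#'   0.1).
#' @return A tibble of blocks: `contig`, `start`, `end`, `label`
#'   (`"A"`, `"B"`, `"ambiguous"`), `n_bins`.
#' @export
call_blocks <- function(bins_a, bins_b, margin = 0.1) {
  stopifnot(inherits(bins_a, "binned_track"), inherits(bins_b, "binned_track"))
  if (!identical(bins_a$contig, bins_b$contig) ||
      !identical(bins_a$bin_start, bins_b$bin_start) ||
      !identical(bins_a$bin_end, bins_b$bin_end))
    stop("bin grids of the two tracks do not match", call. = FALSE)
  a <- bins_a$mean_conservation
  b <- bins_b$mean_conservation
  label <- rep("ambiguous", length(a))
  ok <- !is.na(a) & !is.na(b)
  label[ok & (a - b > margin)] <- "A"
  label[ok & (b - a > margin)] <- "B"
  if (length(label) == 0)
    return(tibble::tibble(contig = character(0), start = integer(0),
                          end = integer(0), label = character(0),
                          n_bins = integer(0)))
  new_run <- c(TRUE, bins_a$contig[-1] != bins_a$contig[-length(label)] |
                 label[-1] != label[-length(label)])
  run <- cumsum(new_run)
  blk_contig <- as.character(tapply(bins_a$contig, run, `[`, 1))
  blk_start <- as.integer(tapply(bins_a$bin_start, run, min))
  blk_end <- as.integer(tapply(bins_a$bin_end, run, max))
  blk_label <- as.character(tapply(label, run, `[`, 1))
  blk_n <- as.integer(tapply(label, run, length))
  tibble::tibble(contig = blk_contig, start = blk_start, end = blk_end,
                 label = blk_label, n_bins = blk_n)
}

#' Plot binned conservation along contigs
#'
#' @param object A `binned_track`.
#' @param ... Unused.
#' @return A ggplot object, one facet per contig.
#' @export
autoplot.binned_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes((.data$bin_start + .data$bin_end) / 2,
                                   .data$mean_conservation)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "mean k-mer conservation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
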