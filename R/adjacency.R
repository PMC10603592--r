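#' @title Pairwise adjacency statistics
#' @description
#' Each genome column of the index is a set of canonical k-mers, so pairwise
#' similarity reduces to set arithmetic on bit columns. The base statistic
#' is the shared-k-mer count |Ki n Kj|; from it derive Jaccard similarity,
#' ANI (via the Mash transform), and MerQury-style quality values (QV),
#' either directional or the symmetric union-denominator variant.
#' A `kmer_adjacency` holds the |G| x |G| matrix of one statistic plus the
#' genome order, k, and the per-genome distinct k-mer counts needed for the
#' conversions.
#' @name kmer_adjacency
NULL

new_adjacency <- function(values, stat, k, genome_ids, per_genome_counts) {
  dimnames(values) <- list(genome_ids, genome_ids)
  structure(
    list(values = values, stat = stat, k = as.integer(k),
         genome_ids = as.character(genome_ids),
         per_genome_counts = setNames(as.numeric(per_genome_counts),
                                      genome_ids)),
    class = "kmer_adjacency"
  )
}

#' Shared k-mer counts between all genome pairs
#'
#' Entry (i, j) is |Ki n Kj|, the number of canonical k-mers present in both
#' genomes, computed by bitwise column intersection over the presence block.
#' The diagonal equals each genome's distinct k-mer count.
#'
#' @param index A [kmer_index].
#' @return A `kmer_adjacency` with `stat = "shared_count"`.
#' @export
shared_kmer_matrix <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  G <- length(index$genome_ids)
  vals <- .kc_shared_counts(index$presence, index$n_kmers, G)
  new_adjacency(vals, "shared_count", index$k, index$genome_ids,
                index$per_genome_counts)
}

#' Convert shared counts to Jaccard similarity
#'
#' J(i, j) = |Ki n Kj| / |Ki u Kj|. A genome with zero k-mers has an
#' undefined Jaccard against every other genome; those entries are `NA`,
#' never 0.
#'
#' @param shared A `kmer_adjacency` with `stat = "shared_count"`.
#' @return A `kmer_adjacency` with `stat = "jaccard"`; diagonal 1 where
#'   defined.
#' @export
to_jaccard <- function(shared) {
  stopifnot(inherits(shared, "kmer_adjacency"))
  if (shared$stat != "shared_count")
    stop("to_jaccard() needs a shared_count matrix, got ", shared$stat,
         call. = FALSE)
  n <- shared$per_genome_counts
  union <- outer(n, n, `+`) - shared$values
  vals <- ifelse(union > 0, shared$values / union, NA_real_)
  empty <- which(n == 0)
  vals[empty, ] <- NA_real_
  vals[, empty] <- NA_real_
  new_adjacency(vals, "jaccard", shared$k, shared$genome_ids, n)
}

#' Convert Jaccard similarity to ANI
#'
#' Applies the Mash transform from k-mer Jaccard to average nucleotide
#' identity: `ANI% = 100 * (1 + ln(2J / (1 + J)) / k)`, clamped below at 0.
#' It is strictly increasing in J with ANI(J=1) = 100. J = 0 carries no
#' identity information under this transform (the log diverges) and is
#' reported `NA`.
#'
#' @param jaccard A `kmer_adjacency` with `stat = "jaccard"`.
#' @param k K-mer size; defaults to the matrix's own k.
#' @return A `kmer_adjacency` with `stat = "ani_percent"` on the percent
#'   scale (diagonal 100).
#' @export
to_ani <- function(jaccard, k = NULL) {
  stopifnot(inherits(jaccard, "kmer_adjacency"))
  if (jaccard$stat != "jaccard")
    stop("to_ani() needs a jaccard matrix, got ", jaccard$stat, call. = FALSE)
  k <- k %||% jaccard$k
  J <- jaccard$values
  vals <- ifelse(!is.na(J) & J > 0,
                 100 * (1 + log(2 * J / (1 + J)) / k),
                 NA_real_)
  vals <- pmax(vals, 0)
  new_adjacency(vals, "ani_percent", k, jaccard$genome_ids,
                jaccard$per_genome_counts)
}

#' Convert shared counts to MerQury-style quality values
#'
#' Directional QV treats genome i as query and j as reference: the fraction
#' of i's k-mers found in j gives a per-base error estimate
#' `E = 1 - (|Ki n Kj| / |Ki|)^(1/k)` and `QV = -10 log10(E)`. The
#' symmetric variant replaces |Ki| with |Ki u Kj|, which is symmetric by
#' construction and reduces to the directional value when the two k-mer
#' sets coincide. Perfect agreement (E = 0) is reported as the cap value 99,
#' a finite, sortable sentinel; zero sharing gives QV = 0; a genome with no
#' k-mers gives `NA`.
#'
#' @param shared A `kmer_adjacency` with `stat = "shared_count"`.
#' @param symmetric Use the union denominator (default `FALSE`).
#' @param cap QV reported when the error estimate is exactly 0 (default 99).
#' @return A `kmer_adjacency` with `stat = "qv_directional"` or
#'   `"qv_symmetric"`.
#' @export
to_qv <- function(shared, symmetric = FALSE, cap = 99) {
  stopifnot(inherits(shared, "kmer_adjacency"))
  if (shared$stat != "shared_count")
    stop("to_qv() needs a shared_count matrix, got ", shared$stat,
         call. = FALSE)
  n <- shared$per_genome_counts
  k <- shared$k
  denom <- if (symmetric) outer(n, n, `+`) - shared$values
           else matrix(n, nrow = length(n), ncol = length(n))
  frac <- ifelse(denom > 0, shared$values / denom, NA_real_)
  E <- 1 - frac^(1 / k)
  vals <- ifelse(is.na(E), NA_real_, ifelse(E <= 0, cap, -10 * log10(E)))
  new_adjacency(vals, if (symmetric) "qv_symmetric" else "qv_directional",
                k, shared$genome_ids, n)
}

#' One-call adjacency matrix in any supported statistic
#'
#' @param index A [kmer_index].
#' @param stat One of `"shared"`, `"jaccard"`, `"ani"`, `"qv"`, `"qv-sym"`.
#' @return A `kmer_adjacency`.
#' @export
adjacency_matrix <- function(index,
                             stat = c("shared", "jaccard", "ani", "qv", "qv-sym")) {
  stat <- match.arg(stat)
  shared <- shared_kmer_matrix(index)
  switch(stat,
    "shared" = shared,
    "jaccard" = to_jaccard(shared),
    "ani" = to_ani(to_jaccard(shared)),
    "qv" = to_qv(shared, symmetric = FALSE),
    "qv-sym" = to_qv(shared, symmetric = TRUE)
  )
}

#' Tidy an adjacency matrix into long pair form
#'
#' @param x A `kmer_adjacency`.
#' @param ... Unused.
#' @return A tibble with columns `genome_1`, `genome_2`, `stat`, `value`
#'   (all ordered pairs, including the diagonal).
#' @export
tidy.kmer_adjacency <- function(x, ...) {
  g <- x$genome_ids
  tibble::tibble(
    genome_1 = rep(g, times = length(g)),
    genome_2 = rep(g, each = length(g)),
    stat = x$stat,
    value = as.vector(x$values)
  )
}

#' @export
print.kmer_adjacency <- function(x, ...) {
  cat("<kmer_adjacency>", x$stat, "over", length(x$genome_ids), "genomes, k =",
      x$k, "\n")
  print(round(x$values, 4))
  invisible(x)
}

adjacency_distance <- function(adj) {
  switch(adj$stat,
    "jaccard" = 1 - adj$values,
    "ani_percent" = (100 - adj$values) / 100,
    "shared_count" = 1 - to_jaccard(adj)$values,
    stop("clustering needs a symmetric statistic (jaccard, ani, or shared); got ",
         adj$stat, call. = FALSE)
  )
}

#' Hierarchically cluster genomes by adjacency
#'
#' Agglomerative clustering with average linkage (UPGMA) on the distance
#' implied by the statistic: 1 - J for Jaccard (shared counts are first
#' converted to Jaccard so the ordering is scale-free) and (100 - ANI)/100
#' for ANI. Leaf order is deterministic for fixed input; permuting the
#' input genome order permutes labels but not the tree topology.
#'
#' @param adj A symmetric `kmer_adjacency` (>= 2 genomes).
#' @return A list with `order` (genome ids in leaf order) and `hclust` (the
#'   [stats::hclust] tree).
#' @export
cluster_genomes <- function(adj) {
  stopifnot(inherits(adj, "kmer_adjacency"))
  if (length(adj$genome_ids) < 2)
    stop("clustering needs at least 2 genomes", call. = FALSE)
  d <- adjacency_distance(adj)
  if (anyNA(d))
    stop("cannot cluster: undefined (NA) adjacency entries present",
         call. = FALSE)
  hc <- hclust(as.dist(d), method = "average")
  list(order = adj$genome_ids[hc$order], hclust = hc)
}

#' Heatmap of an adjacency matrix
#'
#' @param object A `kmer_adjacency`.
#' @param cluster Reorder rows/columns by [cluster_genomes()] leaf order
#'   (default `TRUE` when the statistic supports it).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kmer_adjacency <- function(object, cluster = TRUE, ...) {
  ord <- object$genome_ids
  if (cluster && length(ord) >= 2 &&
      object$stat %in% c("jaccard", "ani_percent", "shared_count") &&
      !anyNA(adjacency_distance(object))) {
    ord <- cluster_genomes(object)$order
  }
  df <- tidy(object) |>
    dplyr::mutate(
      genome_1 = factor(.data$genome_1, levels = ord),
      genome_2 = factor(.data$genome_2, levels = rev(ord))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_1, .data$genome_2,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$stat) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write an adjacency matrix as TSV
#'
#' Genome ids form the first row and first column; numeric values are
#' written with 4 decimals (shared counts as integers); undefined entries
#' as `NA`. Optional leading `#` provenance lines.
#'
#' @param adj A `kmer_adjacency`; if `cluster = TRUE` rows/columns are
#'   reordered by clustering leaf order first.
#' @param path Output path.
#' @param cluster Reorder by [cluster_genomes()] (default `FALSE`).
#' @param provenance Character vector of comment lines to prepend (written
#'   as `# ...`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(adj, path, cluster = FALSE, provenance = NULL) {
  stopifnot(inherits(adj, "kmer_adjacency"))
  vals <- adj$values
  if (cluster) {
    ord <- cluster_genomes(adj)$order
    vals <- vals[ord, ord, drop = FALSE]
  }
  fmt <- if (adj$stat == "shared_count") format(vals, trim = TRUE, scientific = FALSE)
         else formatC(vals, format = "f", digits = 4)
  fmt[is.na(vals)] <- "NA"
  lines <- c(
    if (length(provenance)) paste0("# ", provenance),
    paste(c("genome_id", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)),
           function(i) paste(c(rownames(vals)[i], fmt[i, ]), collapse = "\t"),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
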