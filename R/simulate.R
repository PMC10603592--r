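#' @title Synthetic pangenome generator
#' @description
#' Seeded generator of toy pangenomes with known divergence structure: a
#' random ancestral sequence is mutated independently per genome (star
#' phylogeny) with SNPs, short INDELs, optional structural variants and
#' N-gap runs, plus donor-to-recipient introgression blocks copied from a
#' separately diverged donor lineage. Every event is recorded in a ground
#' truth object, making the generator the fixture factory for the whole
#' toolkit — block-caller accuracy, survival laws and similarity patterns
#' can all be checked against known coordinates. One master seed fans out
#' to per-genome substreams, so adding a genome never perturbs the others.
#' @name synthetic_pangenome
NULL

BASES <- c("A", "C", "G", "T")

#' Simulate a pangenome from a common ancestor
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Ancestor length in bp.
#' @param seed Master seed; the same seed yields byte-identical FASTA
#'   output.
#' @param snp_rate Per-bp substitution probability per genome.
#' @param indel_rate Per-bp probability of starting an indel; each indel is
#'   a deletion or insertion with equal probability.
#' @param indel_mean Mean indel length (geometric distribution, min 1).
#' @param sv_events Optional tibble/data.frame of structural variants with
#'   columns `genome` (1-based index or genome id), `type` (one of
#'   `"deletion"`, `"insertion"`, `"duplication"`, `"inversion"`), `start`
#'   (0-based, ancestor coordinates) and `length`.
#' @param introgressions Optional tibble/data.frame with columns
#'   `recipient` (1-based index or genome id), `start` (0-based) and
#'   `length`: the recipient's interval is replaced by the donor lineage's
#'   sequence over the same ancestral interval. Out-of-bounds intervals
#'   are an error.
#' @param donor_divergence SNP rate of the donor lineage relative to the
#'   ancestor (SNP-only, so ancestor coordinates stay aligned).
#' @param n_gap_rate Per-bp probability of opening a run of Ns (geometric
#'   length, mean 20).
#' @param out_dir Optional directory; when given, one FASTA per genome and
#'   a `truth.json` are written there.
#' @return A list: `genomes` tibble (`genome_id`, `length`, `path` when
#'   written), `sequences` (named list of genome strings, plus the
#'   untouched `ancestor` and, when used, `donor`), and `truth` (per-genome
#'   event records with coordinates).
#' @export
simulate_pangenome <- function(n_genomes = 3, genome_length = 5000, seed = 1,
                               snp_rate = 0.002, indel_rate = 0,
                               indel_mean = 3, sv_events = NULL,
                               introgressions = NULL, donor_divergence = 0.02,
                               n_gap_rate = 0, out_dir = NULL) {
  stopifnot(n_genomes >= 1, genome_length >= 1,
            snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            n_gap_rate >= 0, n_gap_rate <= 1)
  set.seed(seed)
  ancestor <- sample(BASES, genome_length, replace = TRUE)
  streams <- sample.int(.Machine$integer.max - 1L, n_genomes + 1L)
  donor_seed <- streams[1]
  genome_seeds <- streams[-1]

  need_donor <- !is.null(introgressions) && nrow(introgressions) > 0
  donor <- NULL
  if (need_donor) {
    set.seed(donor_seed)
    donor <- mutate_snps(ancestor, donor_divergence)$seq
  }

  ids <- sprintf("g%02d", seq_len(n_genomes))
  truth <- vector("list", n_genomes)
  seqs <- vector("list", n_genomes)
  for (g in seq_len(n_genomes)) {
    set.seed(genome_seeds[g])
    s <- ancestor
    events <- list()

    if (need_donor) {
      intro_g <- introgressions[match_genome(introgressions$recipient, g, ids), ,
                                drop = FALSE]
      for (i in seq_len(nrow(intro_g))) {
        st <- intro_g$start[i]; len <- intro_g$length[i]
        if (st < 0 || st + len > genome_length)
          stop("introgression [", st, ", ", st + len,
               ") outside sequence bounds [0, ", genome_length, ")",
               call. = FALSE)
        s[(st + 1):(st + len)] <- donor[(st + 1):(st + len)]
        events <- c(events, list(list(type = "introgression", start = st,
                                      length = len)))
      }
    }

    sn <- mutate_snps(s, snp_rate)
    s <- sn$seq
    if (length(sn$pos))
      events <- c(events, list(list(type = "snp", positions = sn$pos - 1L)))

    if (indel_rate > 0) {
      idl <- mutate_indels(s, indel_rate, indel_mean)
      s <- idl$seq
      events <- c(events, idl$events)
    }

    if (!is.null(sv_events) && nrow(sv_events) > 0) {
      sv_g <- sv_events[match_genome(sv_events$genome, g, ids), , drop = FALSE]
      for (i in seq_len(nrow(sv_g))) {
        res <- apply_sv(s, sv_g$type[i], sv_g$start[i], sv_g$length[i])
        s <- res$seq
        events <- c(events, list(res$event))
      }
    }

    if (n_gap_rate > 0) {
      gp <- mutate_ngaps(s, n_gap_rate)
      s <- gp$seq
      events <- c(events, gp$events)
    }

    seqs[[g]] <- paste(s, collapse = "")
    truth[[g]] <- list(genome_id = ids[g], events = events)
  }
  names(seqs) <- ids

  out <- list(
    genomes = tibble::tibble(genome_id = ids,
                             length = nchar(unlist(seqs, use.names = FALSE))),
    sequences = c(seqs, list(ancestor = paste(ancestor, collapse = "")),
                  if (need_donor) list(donor = paste(donor, collapse = ""))),
    truth = list(seed = seed, genome_length = genome_length,
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 n_gap_rate = n_gap_rate, genomes = truth)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(ids, ".fa"))
    for (g in seq_len(n_genomes))
      write_fasta(setNames(seqs[g], ids[g]), paths[g])
    jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$genomes$path <- paths
  }
  out
}

match_genome <- function(col, g, ids) {
  if (is.numeric(col)) which(col == g) else which(col == ids[g])
}

# substitute each base independently with prob rate; returns 1-based positions
mutate_snps <- function(chars, rate) {
  if (rate <= 0) return(list(seq = chars, pos = integer(0)))
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    # replace with a uniformly chosen different base
    shift <- sample.int(3L, length(hit), replace = TRUE)
    old <- match(chars[hit], BASES)
    chars[hit] <- BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  list(seq = chars, pos = hit)
}

mutate_indels <- function(chars, rate, mean_len) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (!length(hit)) return(list(seq = chars, events = list()))
  is_del <- stats::runif(length(hit)) < 0.5
  lens <- stats::rgeom(length(hit), 1 / mean_len) + 1L
  events <- list()
  # apply right-to-left so earlier coordinates stay valid
  pieces <- chars
  for (i in rev(seq_along(hit))) {
    p <- hit[i]; len <- lens[i]
    if (is_del[i]) {
      to <- min(p + len - 1L, length(pieces))
      pieces <- pieces[-(p:to)]
      events <- c(events, list(list(type = "deletion", start = p - 1L,
                                    length = to - p + 1L)))
    } else {
      ins <- sample(BASES, len, replace = TRUE)
      pieces <- append(pieces, ins, after = p)
      events <- c(events, list(list(type = "insertion", start = p - 1L,
                                    length = len,
                                    alt = paste(ins, collapse = ""))))
    }
  }
  list(seq = pieces, events = rev(events))
}

apply_sv <- function(chars, type, start, len) {
  L <- length(chars)
  if (start < 0 || start + len > L)
    stop("SV [", start, ", ", start + len, ") outside sequence bounds [0, ",
         L, ")", call. = FALSE)
  idx <- (start + 1):(start + len)
  ev <- list(type = type, start = start, length = len)
  seq_out <- switch(type,
    deletion = chars[-idx],
    insertion = append(chars, sample(BASES, len, replace = TRUE), after = start),
    duplication = append(chars, chars[idx], after = start + len),
    inversion = { chars[idx] <- rev(chartr_vec(chars[idx])); chars },
    stop("unknown SV type: ", type, call. = FALSE)
  )
  list(seq = seq_out, event = ev)
}

chartr_vec <- function(x) c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]

mutate_ngaps <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (!length(hit)) return(list(seq = chars, events = list()))
  lens <- stats::rgeom(length(hit), 1 / 20) + 1L
  events <- list()
  for (i in seq_along(hit)) {
    to <- min(hit[i] + lens[i] - 1L, length(chars))
    chars[hit[i]:to] <- "N"
    events <- c(events, list(list(type = "n_gap", start = hit[i] - 1L,
                                  length = to - hit[i] + 1L)))
  }
  list(seq = chars, events = events)
}

#' The standard two-panel + hybrid toy fixture
#'
#' Builds the canonical end-to-end test input: two panels of genomes
#' diverged from a common ancestor through two founders (panel A, 4
#' genomes; panel B, 3 genomes) plus one hybrid genome — a panel-A lineage
#' carrying two known introgression blocks copied from the panel-B founder
#' (40 kb and 20 kb on a 200 kb genome by default). Founders diverge from
#' the ancestor by SNPs only (1%), keeping ancestor coordinates aligned so
#' the recorded block coordinates are exact in the hybrid; panel members
#' add 0.25% SNPs and sparse short indels, and the hybrid adds 0.25% SNPs.
#' This mimics, at toy scale, a recent inter-species hybridization: the
#' hybrid is the similarity outlier within its own panel and unusually
#' close to the other panel, with its introgressed loci showing inverted
#' conservation against the two panels.
#'
#' @param seed Master seed.
#' @param out_dir Optional directory for FASTA files + `truth.json`.
#' @param genome_length Genome length in bp (default 200000).
#' @param n_panel_a,n_panel_b Panel sizes (default 4 and 3).
#' @param founder_divergence,member_divergence SNP rates ancestor->founder
#'   and founder->member (defaults 0.01 and 0.0025).
#' @param member_indel_rate Indel rate for panel members (default 1e-4).
#' @param introgressions Tibble with `start` and `length` (0-based, bp) of
#'   the donor blocks carried by the hybrid; defaults to 40 kb at 50 kb
#'   and 20 kb at 140 kb, scaled if `genome_length` differs from 200 kb.
#' @return A list: `genomes` tibble (`genome_id`, `panel`, `length`,
#'   `path` when written), `sequences` (named list incl. founders),
#'   `hybrid_id`, `panel_a`, `panel_b` (genome id vectors),
#'   `introgressions` tibble (`start`, `end`, `length`) and `truth`.
#' @export
make_hybrid_fixture <- function(seed = 1, out_dir = NULL,
                                genome_length = 200000,
                                n_panel_a = 4, n_panel_b = 3,
                                founder_divergence = 0.01,
                                member_divergence = 0.0025,
                                member_indel_rate = 1e-4,
                                introgressions = NULL) {
  if (is.null(introgressions)) {
    scale <- genome_length / 200000
    introgressions <- tibble::tibble(
      start = as.integer(c(50000, 140000) * scale),
      length = as.integer(c(40000, 20000) * scale)
    )
  }
  if (any(introgressions$start < 0 |
          introgressions$start + introgressions$length > genome_length))
    stop("introgression outside sequence bounds", call. = FALSE)

  set.seed(seed)
  ancestor <- sample(BASES, genome_length, replace = TRUE)
  n_members <- n_panel_a + n_panel_b
  streams <- sample.int(.Machine$integer.max - 1L, 2L + n_members + 1L)

  set.seed(streams[1]); founder_a <- mutate_snps(ancestor, founder_divergence)$seq
  set.seed(streams[2]); founder_b <- mutate_snps(ancestor, founder_divergence)$seq

  ids_a <- sprintf("A%02d", seq_len(n_panel_a))
  ids_b <- sprintf("B%02d", seq_len(n_panel_b))
  hybrid_id <- "H01"
  seqs <- list()
  diverge_member <- function(founder) {
    s <- mutate_snps(founder, member_divergence)$seq
    if (member_indel_rate > 0)
      s <- mutate_indels(s, member_indel_rate, 3)$seq
    paste(s, collapse = "")
  }
  for (i in seq_len(n_panel_a)) {
    set.seed(streams[2 + i])
    seqs[[ids_a[i]]] <- diverge_member(founder_a)
  }
  for (i in seq_len(n_panel_b)) {
    set.seed(streams[2 + n_panel_a + i])
    seqs[[ids_b[i]]] <- diverge_member(founder_b)
  }
  # hybrid: panel-A lineage with donor (founder B) blocks, SNPs only so the
  # recorded block coordinates are exact in hybrid coordinates
  set.seed(streams[2 + n_members + 1])
  h <- founder_a
  for (i in seq_len(nrow(introgressions))) {
    st <- introgressions$start[i]; len <- introgressions$length[i]
    h[(st + 1):(st + len)] <- founder_b[(st + 1):(st + len)]
  }
  seqs[[hybrid_id]] <- paste(mutate_snps(h, member_divergence)$seq,
                             collapse = "")

  ids <- c(ids_a, hybrid_id, ids_b)
  panel <- c(rep("A", n_panel_a), "A", rep("B", n_panel_b))
  genomes <- tibble::tibble(genome_id = ids, panel = panel,
                            length = nchar(unlist(seqs[ids], use.names = FALSE)))
  intro_tbl <- tibble::tibble(start = introgressions$start,
                              end = introgressions$start + introgressions$length,
                              length = introgressions$length)
  truth <- list(seed = seed, genome_length = genome_length,
                hybrid_id = hybrid_id, panel_a = c(ids_a, hybrid_id),
                panel_b = ids_b,
                founder_divergence = founder_divergence,
                member_divergence = member_divergence,
                introgressions = intro_tbl)
  out <- list(genomes = genomes,
              sequences = c(seqs, list(ancestor = paste(ancestor, collapse = ""),
                                       founder_a = paste(founder_a, collapse = ""),
                                       founder_b = paste(founder_b, collapse = ""))),
              hybrid_id = hybrid_id, panel_a = ids_a, panel_b = ids_b,
              introgressions = intro_tbl, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(ids, ".fa"))
    for (i in seq_along(ids))
      write_fasta(setNames(seqs[ids[i]], ids[i]), paths[i])
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$genomes$path <- paths
  }
  out
}
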