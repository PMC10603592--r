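#' Encode k-mers as 2-bit integer codes
#'
#' Each k-mer is packed into an unsigned 64-bit integer with two bits per
#' base (A=0, C=1, G=2, T=3), the 5'-most base occupying the most significant
#' bit pair. Under this encoding integer order coincides with lexicographic
#' order on the k-mer string, so the canonical (lexicographically first) form
#' of a k-mer/reverse-complement pair is simply the smaller code.
#'
#' Codes are returned as doubles. They are exact for k <= 26 (codes below
#' 2^53); at k = 27-31 the returned double may round the low bits, so the
#' index machinery never passes codes through R numerics — it keeps them in a
#' compact 64-bit byte representation internally.
#'
#' @param kmers Character vector of k-mer strings (A/C/G/T, case-insensitive;
#'   all the same length).
#' @param k Odd integer in \[3, 31\]; defaults to the length of the first
#'   k-mer.
#' @return Numeric vector of integer codes.
#' @examples
#' kmer_encode(c("ACG", "AAA", "TTT"))  # 6, 0, 63
#' @export
kmer_encode <- function(kmers, k = NULL) {
  kmers <- toupper(as.character(kmers))
  if (length(kmers) == 0) return(numeric(0))
  if (is.null(k)) k <- nchar(kmers[[1]])
  .kc_encode(kmers, as.integer(k))
}

#' Decode integer codes back to k-mer strings
#'
#' Inverse of [kmer_encode()]: `kmer_decode(kmer_encode(w), k) == w`.
#'
#' @param codes Numeric vector of k-mer codes (values in \[0, 4^k)).
#' @param k Odd integer in \[3, 31\].
#' @return Character vector of uppercase k-mer strings.
#' @export
kmer_decode <- function(codes, k) {
  .kc_decode(as.numeric(codes), as.integer(k))
}

#' Reverse complement of a k-mer code
#'
#' An involution on code space: `kmer_revcomp(kmer_revcomp(c, k), k) == c`.
#'
#' @inheritParams kmer_decode
#' @return Numeric vector of reverse-complement codes.
#' @export
kmer_revcomp <- function(codes, k) {
  .kc_revcomp(as.numeric(codes), as.integer(k))
}

#' Canonical form of a k-mer code
#'
#' Of a k-mer and its reverse complement, the canonical form is the
#' lexicographically first, i.e. `min(code, revcomp(code))` under the 2-bit
#' encoding. Idempotent. For odd k no k-mer equals its own reverse
#' complement, so the canonical code space has exactly 4^k / 2 elements.
#'
#' @inheritParams kmer_decode
#' @return Numeric vector of canonical codes.
#' @export
kmer_canonical <- function(codes, k) {
  .kc_canonicalize(as.numeric(codes), as.integer(k))
}

#' Extract canonical k-mers from a sequence
#'
#' Slides a window of width `k` along the sequence and emits the canonical
#' code of every window consisting solely of A/C/G/T (case-insensitive).
#' Windows containing any other character (N, IUPAC ambiguity codes, gaps)
#' are skipped: ambiguity is never expanded. A sequence shorter than `k`
#' yields zero rows.
#'
#' @param sequence A single nucleotide string.
#' @param k Odd integer in \[3, 31\].
#' @return A tibble with columns `pos` (0-based window start, strictly
#'   increasing), `code` (canonical code as double; see [kmer_encode()] for
#'   precision notes) and `kmer` (canonical k-mer string, decoded from the
#'   exact 64-bit code and therefore exact at every k).
#' @examples
#' kmer_extract("ACGTA", 3)
#' @export
kmer_extract <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  res <- .kc_extract(sequence, as.integer(k))
  tibble::tibble(
    pos = as.integer(res$pos),
    code = res$code,
    kmer = res$kmer
  )
}

#' Partition the canonical k-mer space into segments
#'
#' Tiles the theoretical code space \[0, 4^k) with `n` contiguous, disjoint,
#' equal-width half-open ranges (the last segment absorbs the remainder).
#' Segments are the unit of memory-bounded index construction: each build
#' round only materialises the k-mers of one segment. Membership of a code
#' in a segment is O(1) via [kmer_segment_of()].
#'
#' @param k Odd integer in \[3, 31\].
#' @param n Number of segments, `1 <= n <= 4^k`.
#' @return A tibble with columns `ordinal` (0-based), `lo` (inclusive) and
#'   `hi` (exclusive). Bounds are reported as doubles; for k > 26 they are
#'   display values — segment assignment inside the build is exact 64-bit.
#' @export
kmer_segments <- function(k, n) {
  b <- .kc_segment_bounds(as.integer(k), as.integer(n))
  tibble::tibble(ordinal = seq_len(nrow(b)) - 1L, lo = b[, 1], hi = b[, 2])
}

#' Segment ordinal of k-mer codes
#'
#' @param codes Numeric vector of codes in \[0, 4^k).
#' @param k Odd integer in \[3, 31\].
#' @param n Number of segments.
#' @return Integer vector of 0-based segment ordinals.
#' @export
kmer_segment_of <- function(codes, k, n) {
  .kc_segment_of(as.numeric(codes), as.integer(k), as.integer(n))
}
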