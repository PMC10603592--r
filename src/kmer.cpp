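// Canonical k-mer arithmetic and index kernels.
//
// K-mer codes are unsigned 64-bit integers: 2 bits per base, A=0 C=1 G=2 T=3,
// the 5'-most base in the most significant bit pair. For k <= 31 a code fits
// in 62 bits. Codes cross the R boundary either as doubles (exact for
// k <= 26) or, inside an index, as little-endian 8-byte units of a raw
// vector, which is exact for every supported k.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t kspace(int k) {
  return 1ULL << (2 * k);  // 4^k, k <= 31
}

static void check_k(int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer in [3, 31], got %d", k);
}

static inline uint64_t dbl2code(double x) {
  if (!(x >= 0) || x != std::floor(x))
    stop("k-mer code must be a non-negative integer value");
  return (uint64_t) x;
}

// Store / load little-endian 8-byte code units in a raw buffer.
static inline void store_le(unsigned char* p, uint64_t v) {
  for (int b = 0; b < 8; ++b) { p[b] = (unsigned char)(v & 0xFF); v >>= 8; }
}
static inline uint64_t load_le(const unsigned char* p) {
  uint64_t v = 0;
  for (int b = 7; b >= 0; --b) v = (v << 8) | (uint64_t) p[b];
  return v;
}

// [[Rcpp::export(name = ".kc_encode")]]
NumericVector kc_encode(CharacterVector kmers, int k) {
  check_k(k);
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int) std::strlen(s) != k)
      stop("k-mer %d has length %d, expected k = %d", (int) i + 1,
           (int) std::strlen(s), k);
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2code(s[j]);
      if (b < 0)
        stop("invalid base '%c' at position %d of k-mer %d (only A/C/G/T)",
             s[j], j + 1, (int) i + 1);
      code = (code << 2) | (uint64_t) b;
    }
    out[i] = (double) code;
  }
  return out;
}

// [[Rcpp::export(name = ".kc_decode")]]
CharacterVector kc_decode(NumericVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = dbl2code(codes[i]);
    if (code >= kspace(k)) stop("code %.0f out of range for k = %d", codes[i], k);
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = CODE2BASE[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".kc_revcomp")]]
NumericVector kc_revcomp(NumericVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = dbl2code(codes[i]);
    if (code >= kspace(k)) stop("code %.0f out of range for k = %d", codes[i], k);
    out[i] = (double) rc_code(code, k);
  }
  return out;
}

// [[Rcpp::export(name = ".kc_canonicalize")]]
NumericVector kc_canonicalize(NumericVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = dbl2code(codes[i]);
    if (code >= kspace(k)) stop("code %.0f out of range for k = %d", codes[i], k);
    uint64_t rc = rc_code(code, k);
    out[i] = (double) (rc < code ? rc : code);
  }
  return out;
}

// Rolling scan of one sequence: emit (0-based position, canonical code) for
// every window of k A/C/G/T bases; windows touching any other character are
// skipped. Shared by extraction and index construction.
template <typename EMIT>
static void scan_sequence(const char* s, size_t len, int k, EMIT emit) {
  if (len < (size_t) k) return;
  const uint64_t mask = kspace(k) - 1ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int have = 0;  // valid bases accumulated in current run
  for (size_t i = 0; i < len; ++i) {
    int b = base2code(s[i]);
    if (b < 0) { have = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rev = (rev >> 2) | ((3ULL - (uint64_t) b) << shift);
    if (++have >= k) {
      uint64_t canon = rev < fwd ? rev : fwd;
      emit(i + 1 - (size_t) k, canon);
    }
  }
}

// Emits exact canonical k-mer strings alongside double codes: the double
// view rounds above 2^53 (k >= 27), so strings must come from the uint64.
// [[Rcpp::export(name = ".kc_extract")]]
List kc_extract(std::string seq, int k) {
  check_k(k);
  std::vector<double> pos;
  std::vector<double> code;
  std::vector<std::string> kmer;
  std::string buf((size_t) k, 'A');
  scan_sequence(seq.c_str(), seq.size(), k, [&](size_t p, uint64_t c) {
    pos.push_back((double) p);
    code.push_back((double) c);
    uint64_t v = c;
    for (int j = k - 1; j >= 0; --j) { buf[(size_t) j] = CODE2BASE[v & 3ULL]; v >>= 2; }
    kmer.push_back(buf);
  });
  return List::create(_["pos"] = wrap(pos), _["code"] = wrap(code),
                      _["kmer"] = wrap(kmer));
}

// Segment bounds for tiling [0, 4^k) into n equal-width ranges; the last
// segment absorbs the remainder.
static inline void seg_bounds(int k, int n, int ordinal, uint64_t& lo, uint64_t& hi) {
  uint64_t space = kspace(k);
  uint64_t width = space / (uint64_t) n;
  lo = width * (uint64_t) ordinal;
  hi = (ordinal == n - 1) ? space : lo + width;
}

// [[Rcpp::export(name = ".kc_segment_bounds")]]
NumericMatrix kc_segment_bounds(int k, int n) {
  check_k(k);
  if (n < 1) stop("n_segments must be >= 1");
  if ((double) n > std::pow(4.0, k)) stop("n_segments exceeds 4^k");
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    uint64_t lo, hi;
    seg_bounds(k, n, i, lo, hi);
    out(i, 0) = (double) lo;
    out(i, 1) = (double) hi;
  }
  return out;
}

// [[Rcpp::export(name = ".kc_segment_of")]]
IntegerVector kc_segment_of(NumericVector codes, int k, int n) {
  check_k(k);
  if (n < 1) stop("n_segments must be >= 1");
  uint64_t space = kspace(k);
  uint64_t width = space / (uint64_t) n;
  R_xlen_t m = codes.size();
  IntegerVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t c = dbl2code(codes[i]);
    if (c >= space) stop("code %.0f out of range for k = %d", codes[i], k);
    uint64_t ord = c / width;
    if (ord >= (uint64_t) n) ord = (uint64_t) n - 1;  // remainder tail
    out[i] = (int) ord;
  }
  return out;
}

// Build one sub-index over a segment of canonical-code space.
// genomes: list of character vectors (contig sequences per genome).
// Returns sorted unique codes (raw, 8 bytes LE each), a bit-packed presence
// block (ceil(G/8) bytes per code row, genome g at byte g/8 bit g%8), and
// per-genome distinct-code counts within the segment.
// [[Rcpp::export(name = ".kc_build_subindex")]]
List kc_build_subindex(List genomes, int k, int ordinal, int n_segments) {
  check_k(k);
  if (n_segments < 1) stop("n_segments must be >= 1");
  if (ordinal < 0 || ordinal >= n_segments) stop("segment ordinal out of range");
  uint64_t lo, hi;
  seg_bounds(k, n_segments, ordinal, lo, hi);

  const int G = genomes.size();
  std::vector< std::vector<uint64_t> > sets((size_t) G);
  for (int g = 0; g < G; ++g) {
    CharacterVector contigs = genomes[g];
    std::vector<uint64_t>& v = sets[(size_t) g];
    for (R_xlen_t c = 0; c < contigs.size(); ++c) {
      const char* s = CHAR(STRING_ELT(contigs, c));
      scan_sequence(s, std::strlen(s), k, [&](size_t, uint64_t code) {
        if (code >= lo && code < hi) v.push_back(code);
      });
    }
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }

  // union of per-genome sorted sets = row codes
  std::vector<uint64_t> rows;
  {
    size_t tot = 0;
    for (int g = 0; g < G; ++g) tot += sets[(size_t) g].size();
    rows.reserve(tot);
    for (int g = 0; g < G; ++g)
      rows.insert(rows.end(), sets[(size_t) g].begin(), sets[(size_t) g].end());
    std::sort(rows.begin(), rows.end());
    rows.erase(std::unique(rows.begin(), rows.end()), rows.end());
  }

  const size_t n_rows = rows.size();
  const size_t row_bytes = (size_t) ((G + 7) / 8);
  RawVector codes_raw(n_rows * 8);
  RawVector presence(n_rows * row_bytes);
  std::memset(RAW(presence), 0, n_rows * row_bytes);
  unsigned char* cp = RAW(codes_raw);
  for (size_t r = 0; r < n_rows; ++r) store_le(cp + 8 * r, rows[r]);

  unsigned char* pp = RAW(presence);
  IntegerVector counts(G);
  for (int g = 0; g < G; ++g) {
    const std::vector<uint64_t>& v = sets[(size_t) g];
    counts[g] = (int) v.size();
    size_t r = 0;
    for (size_t i = 0; i < v.size(); ++i) {
      // rows is a superset of v and both are sorted: advance pointer
      while (rows[r] != v[i]) ++r;
      pp[r * row_bytes + (size_t) (g >> 3)] |= (unsigned char) (1u << (g & 7));
    }
  }

  return List::create(_["codes"] = codes_raw, _["presence"] = presence,
                      _["counts"] = counts, _["n_rows"] = (double) n_rows,
                      _["lo"] = (double) lo, _["hi"] = (double) hi);
}

// [[Rcpp::export(name = ".kc_col_counts")]]
NumericVector kc_col_counts(RawVector presence, double n_rows_d, int G) {
  size_t n_rows = (size_t) n_rows_d;
  size_t row_bytes = (size_t) ((G + 7) / 8);
  const unsigned char* pp = RAW(presence);
  NumericVector out(G);
  for (size_t r = 0; r < n_rows; ++r)
    for (int g = 0; g < G; ++g)
      if (pp[r * row_bytes + (size_t) (g >> 3)] & (1u << (g & 7))) out[g] += 1.0;
  return out;
}

// Pairwise shared-k-mer counts by bitwise column intersection.
// [[Rcpp::export(name = ".kc_shared_counts")]]
NumericMatrix kc_shared_counts(RawVector presence, double n_rows_d, int G) {
  size_t n_rows = (size_t) n_rows_d;
  size_t row_bytes = (size_t) ((G + 7) / 8);
  const unsigned char* pp = RAW(presence);
  NumericMatrix out(G, G);
  std::vector<int> set;
  set.reserve((size_t) G);
  for (size_t r = 0; r < n_rows; ++r) {
    set.clear();
    const unsigned char* row = pp + r * row_bytes;
    for (int g = 0; g < G; ++g)
      if (row[g >> 3] & (1u << (g & 7))) set.push_back(g);
    for (size_t a = 0; a < set.size(); ++a)
      for (size_t b = a; b < set.size(); ++b) {
        out(set[a], set[b]) += 1.0;
        if (a != b) out(set[b], set[a]) += 1.0;
      }
  }
  return out;
}

static inline bool code_in_index(uint64_t code, const unsigned char* cp, size_t n_rows,
                                 size_t& row_out) {
  size_t lo = 0, hi = n_rows;
  while (lo < hi) {
    size_t mid = lo + (hi - lo) / 2;
    uint64_t v = load_le(cp + 8 * mid);
    if (v < code) lo = mid + 1; else hi = mid;
  }
  if (lo < n_rows && load_le(cp + 8 * lo) == code) { row_out = lo; return true; }
  return false;
}

// Per-position conservation of an anchor sequence against a genome subset.
// subset holds 0-based column indices. Returns length max(L-k+1, 0) with NA
// at windows containing non-ACGT bases.
// [[Rcpp::export(name = ".kc_anchor_conservation")]]
NumericVector kc_anchor_conservation(std::string seq, int k, RawVector codes,
                                     RawVector presence, IntegerVector subset,
                                     int G) {
  check_k(k);
  size_t n_rows = (size_t) (codes.size() / 8);
  size_t row_bytes = (size_t) ((G + 7) / 8);
  const unsigned char* cp = RAW(codes);
  const unsigned char* pp = RAW(presence);
  const double denom = (double) subset.size();
  R_xlen_t L = (R_xlen_t) seq.size();
  R_xlen_t n_out = L - k + 1;
  if (n_out < 0) n_out = 0;
  NumericVector out(n_out, NA_REAL);
  scan_sequence(seq.c_str(), seq.size(), k, [&](size_t p, uint64_t code) {
    size_t row;
    double cnt = 0.0;
    if (code_in_index(code, cp, n_rows, row)) {
      const unsigned char* rowp = pp + row * row_bytes;
      for (R_xlen_t i = 0; i < subset.size(); ++i) {
        int g = subset[i];
        if (rowp[g >> 3] & (1u << (g & 7))) cnt += 1.0;
      }
    }
    out[(R_xlen_t) p] = denom > 0 ? cnt / denom : NA_REAL;
  });
  return out;
}

// [[Rcpp::export(name = ".kc_decode_rows")]]
CharacterVector kc_decode_rows(RawVector codes, int k) {
  check_k(k);
  size_t n_rows = (size_t) (codes.size() / 8);
  const unsigned char* cp = RAW(codes);
  CharacterVector out((R_xlen_t) n_rows);
  std::string buf((size_t) k, 'A');
  for (size_t r = 0; r < n_rows; ++r) {
    uint64_t code = load_le(cp + 8 * r);
    for (int j = k - 1; j >= 0; --j) { buf[(size_t) j] = CODE2BASE[code & 3ULL]; code >>= 2; }
    out[(R_xlen_t) r] = buf;
  }
  return out;
}

// Row codes as doubles (exact only below 2^53; used for display/tidy views).
// [[Rcpp::export(name = ".kc_rows_to_double")]]
NumericVector kc_rows_to_double(RawVector codes) {
  size_t n_rows = (size_t) (codes.size() / 8);
  const unsigned char* cp = RAW(codes);
  NumericVector out((R_xlen_t) n_rows);
  for (size_t r = 0; r < n_rows; ++r) out[(R_xlen_t) r] = (double) load_le(cp + 8 * r);
  return out;
}

// Bit for (row, genome); used by tests and column extraction.
// [[Rcpp::export(name = ".kc_presence_col")]]
LogicalVector kc_presence_col(RawVector presence, double n_rows_d, int G, int g) {
  size_t n_rows = (size_t) n_rows_d;
  size_t row_bytes = (size_t) ((G + 7) / 8);
  const unsigned char* pp = RAW(presence);
  LogicalVector out((R_xlen_t) n_rows);
  for (size_t r = 0; r < n_rows; ++r)
    out[(R_xlen_t) r] = (pp[r * row_bytes + (size_t) (g >> 3)] & (1u << (g & 7))) != 0;
  return out;
}

// Verify strict ascending order of concatenated code rows (merge contract).
// [[Rcpp::export(name = ".kc_codes_sorted")]]
bool kc_codes_sorted(RawVector codes) {
  size_t n_rows = (size_t) (codes.size() / 8);
  const unsigned char* cp = RAW(codes);
  for (size_t r = 1; r < n_rows; ++r)
    if (load_le(cp + 8 * r) <= load_le(cp + 8 * (r - 1))) return false;
  return true;
}
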