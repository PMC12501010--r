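// Canonical k-mer index over genome sequences.
//
// K-mers (k odd, k <= 63) are 2-bit packed into a 128-bit key held as two
// uint64s; the canonical form is the lexicographic minimum of the forward
// and reverse-complement encodings. Membership is exact: keys are stored
// in a sorted, deduplicated vector and queried by binary search, so there
// are no false positives. K-mers containing non-ACGT characters are
// skipped on both build and query.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <utility>
#include <vector>

using namespace Rcpp;

typedef std::pair<uint64_t, uint64_t> Key; // (hi, lo)

struct KmerIndex {
  int k;
  std::vector<Key> keys; // sorted, unique
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Collect canonical keys of all valid k-mers of one sequence.
static void collect_keys(const char* s, size_t n, int k,
                         std::vector<Key>& out) {
  if (n < (size_t)k) return;
  const int kk = 2 * k;
  // masks for the high word (bits above 64)
  const int hi_bits = kk > 64 ? kk - 64 : 0;
  const uint64_t hi_mask = hi_bits >= 64 ? ~0ULL
    : (hi_bits == 0 ? 0ULL : ((1ULL << hi_bits) - 1));
  uint64_t fhi = 0, flo = 0, rhi = 0, rlo = 0;
  int run = 0; // valid bases accumulated
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fhi = flo = rhi = rlo = 0; continue; }
    // forward: shift left 2, append c
    fhi = ((fhi << 2) | (flo >> 62)) & (kk > 64 ? hi_mask : 0ULL);
    flo = (flo << 2) | (uint64_t)c;
    if (kk <= 64) { flo &= (kk == 64 ? ~0ULL : ((1ULL << kk) - 1)); fhi = 0; }
    // reverse complement: shift right 2, prepend complement at position 2k-2
    int rc = 3 - c;
    rlo = (rlo >> 2) | (rhi << 62);
    rhi = rhi >> 2;
    int pos = kk - 2; // bit offset of the new base
    if (pos >= 64) rhi |= ((uint64_t)rc) << (pos - 64);
    else rlo |= ((uint64_t)rc) << pos;
    if (++run >= k) {
      Key f(fhi, flo), r(rhi, rlo);
      out.push_back(f < r ? f : r);
    }
  }
}

// [[Rcpp::export]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 63) stop("k must be in 1..63");
  if (k % 2 == 0) stop("k must be odd (even k makes canonicalization ambiguous)");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    collect_keys(s, LENGTH(STRING_ELT(seqs, i)), k, idx->keys);
  }
  std::sort(idx->keys.begin(), idx->keys.end());
  idx->keys.erase(std::unique(idx->keys.begin(), idx->keys.end()),
                  idx->keys.end());
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
double kmer_index_size(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (double)idx->keys.size();
}

// [[Rcpp::export]]
int kmer_index_k(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return idx->k;
}

// Per-sequence coverage: fraction of its k-mers present in the index.
// Returns a 3-column matrix: n_kmers, n_hit, score (NA when n_kmers == 0).
// [[Rcpp::export]]
NumericMatrix kmer_coverage_scores(SEXP xp, CharacterVector seqs) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  NumericMatrix out(seqs.size(), 3);
  std::vector<Key> q;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    q.clear();
    const char* s = CHAR(STRING_ELT(seqs, i));
    collect_keys(s, LENGTH(STRING_ELT(seqs, i)), k, q);
    double n = (double)q.size(), hit = 0;
    for (const Key& key : q) {
      if (std::binary_search(idx->keys.begin(), idx->keys.end(), key)) ++hit;
    }
    out(i, 0) = n;
    out(i, 1) = hit;
    out(i, 2) = n > 0 ? hit / n : NA_REAL;
  }
  colnames(out) = CharacterVector::create("n_kmers", "n_hit", "score");
  return out;
}

// Membership test for explicit k-mer strings (testing hook).
// [[Rcpp::export]]
LogicalVector kmer_index_has(SEXP xp, CharacterVector kmers) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  LogicalVector out(kmers.size());
  std::vector<Key> q;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    q.clear();
    const char* s = CHAR(STRING_ELT(kmers, i));
    if (LENGTH(STRING_ELT(kmers, i)) != k) { out[i] = NA_LOGICAL; continue; }
    collect_keys(s, k, k, q);
    if (q.empty()) { out[i] = false; continue; }
    out[i] = std::binary_search(idx->keys.begin(), idx->keys.end(), q[0]);
  }
  return out;
}
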