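#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// 2-bit DNA encoding; anything outside ACGT (i.e. N) invalidates the window.
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

// Append canonical (min of forward / reverse-complement) k-mers of all
// N-free windows of s to out. k <= 31 so a k-mer fits in 62 bits.
static void collect_canonical(const char* s, size_t n, int k,
                              std::vector<uint64_t>& out) {
  if ((int)n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

struct ColoredIndex {
  int k;
  int n_colors;
  std::vector<uint64_t> kmers;  // sorted, unique canonical k-mers
  std::vector<uint32_t> masks;  // colour bitsets, parallel to kmers
};

// [[Rcpp::export]]
SEXP cpp_build_colored_index(List seqs_by_color, int k) {
  int nc = seqs_by_color.size();
  if (nc < 1) stop("need at least one colour");
  if (nc > 32) stop("at most 32 colours supported");
  if (k < 2 || k > 31) stop("k must be in [2, 31]");

  // Per-colour sorted unique k-mer lists, then a multiway merge.
  std::vector<std::vector<uint64_t>> per(nc);
  for (int c = 0; c < nc; ++c) {
    CharacterVector v = seqs_by_color[c];
    std::vector<uint64_t> km;
    for (int j = 0; j < v.size(); ++j) {
      const char* s = CHAR(STRING_ELT(v, j));
      collect_canonical(s, LENGTH(STRING_ELT(v, j)), k, km);
    }
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    per[c] = std::move(km);
  }

  ColoredIndex* idx = new ColoredIndex();
  idx->k = k;
  idx->n_colors = nc;

  typedef std::pair<uint64_t, int> heap_item;  // (kmer, colour)
  std::priority_queue<heap_item, std::vector<heap_item>,
                      std::greater<heap_item>> heap;
  std::vector<size_t> pos(nc, 0);
  for (int c = 0; c < nc; ++c)
    if (!per[c].empty()) heap.push(std::make_pair(per[c][0], c));

  while (!heap.empty()) {
    uint64_t cur = heap.top().first;
    uint32_t mask = 0;
    while (!heap.empty() && heap.top().first == cur) {
      int c = heap.top().second;
      heap.pop();
      mask |= (1u << c);
      if (++pos[c] < per[c].size())
        heap.push(std::make_pair(per[c][pos[c]], c));
    }
    idx->kmers.push_back(cur);
    idx->masks.push_back(mask);
  }

  XPtr<ColoredIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
double cpp_index_size(SEXP xp_) {
  XPtr<ColoredIndex> xp(xp_);
  return (double)xp->kmers.size();
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp_) {
  XPtr<ColoredIndex> xp(xp_);
  return xp->k;
}

// [[Rcpp::export]]
int cpp_index_n_colors(SEXP xp_) {
  XPtr<ColoredIndex> xp(xp_);
  return xp->n_colors;
}

// For each query sequence, count valid (N-free) k-mer windows and, per
// colour, how many of them are present in that colour. The presence-ratio
// threshold e is applied on the R side.
// [[Rcpp::export]]
List cpp_query_counts(CharacterVector queries, SEXP xp_) {
  XPtr<ColoredIndex> xp(xp_);
  const ColoredIndex& idx = *xp;
  int nq = queries.size(), nc = idx.n_colors;
  IntegerVector m(nq);
  IntegerMatrix counts(nq, nc);
  std::vector<uint64_t> km;
  for (int q = 0; q < nq; ++q) {
    km.clear();
    const char* s = CHAR(STRING_ELT(queries, q));
    collect_canonical(s, LENGTH(STRING_ELT(queries, q)), idx.k, km);
    m[q] = (int)km.size();
    std::vector<int> cnt(nc, 0);
    for (size_t i = 0; i < km.size(); ++i) {
      std::vector<uint64_t>::const_iterator it =
        std::lower_bound(idx.kmers.begin(), idx.kmers.end(), km[i]);
      if (it != idx.kmers.end() && *it == km[i]) {
        uint32_t mask = idx.masks[it - idx.kmers.begin()];
        for (int c = 0; c < nc; ++c)
          if (mask & (1u << c)) ++cnt[c];
      }
    }
    for (int c = 0; c < nc; ++c) counts(q, c) = cnt[c];
  }
  return List::create(_["m"] = m, _["counts"] = counts);
}

// Plain canonical k-mer set (for consensus-QV estimation).
// [[Rcpp::export]]
SEXP cpp_kmer_set(CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::vector<uint64_t>* km = new std::vector<uint64_t>();
  for (int j = 0; j < seqs.size(); ++j)
    collect_canonical(CHAR(STRING_ELT(seqs, j)), LENGTH(STRING_ELT(seqs, j)),
                      k, *km);
  std::sort(km->begin(), km->end());
  km->erase(std::unique(km->begin(), km->end()), km->end());
  XPtr<std::vector<uint64_t>> xp(km, true);
  return xp;
}

// [[Rcpp::export]]
double cpp_kmer_set_size(SEXP xp_) {
  XPtr<std::vector<uint64_t>> xp(xp_);
  return (double)xp->size();
}

// Count total valid k-mer windows (t) in seqs and how many are absent (b)
// from the trusted set.
// [[Rcpp::export]]
NumericVector cpp_count_absent(CharacterVector seqs, SEXP xp_, int k) {
  XPtr<std::vector<uint64_t>> xp(xp_);
  const std::vector<uint64_t>& set = *xp;
  double t = 0, b = 0;
  std::vector<uint64_t> km;
  for (int j = 0; j < seqs.size(); ++j) {
    km.clear();
    collect_canonical(CHAR(STRING_ELT(seqs, j)), LENGTH(STRING_ELT(seqs, j)),
                      k, km);
    t += km.size();
    for (size_t i = 0; i < km.size(); ++i)
      if (!std::binary_search(set.begin(), set.end(), km[i])) b += 1;
  }
  return NumericVector::create(_["t"] = t, _["b"] = b);
}
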