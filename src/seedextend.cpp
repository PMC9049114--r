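#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base2bit_se(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static const int DP_INF = 1 << 28;

// Exact-seed table over all targets: k-mer keys with packed (target, pos)
// values, both sorted by key for binary-search lookup.
struct SeedTable {
  int k;
  std::vector<uint64_t> keys;
  std::vector<uint64_t> vals;  // (target << 40) | pos
};

static void build_seed_table(CharacterVector targets, int k, SeedTable& tab) {
  tab.k = k;
  std::vector<std::pair<uint64_t, uint64_t>> pairs;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int t = 0; t < targets.size(); ++t) {
    const char* s = CHAR(STRING_ELT(targets, t));
    size_t n = LENGTH(STRING_ELT(targets, t));
    if ((int)n < k) continue;
    uint64_t fwd = 0;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      int b = base2bit_se(s[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = i + 1 - k;
        pairs.push_back(std::make_pair(fwd, ((uint64_t)t << 40) | pos));
      }
    }
  }
  std::sort(pairs.begin(), pairs.end());
  tab.keys.resize(pairs.size());
  tab.vals.resize(pairs.size());
  for (size_t i = 0; i < pairs.size(); ++i) {
    tab.keys[i] = pairs[i].first;
    tab.vals[i] = pairs[i].second;
  }
}

// Banded semi-global edit distance: the whole query against a target
// window with free leading/trailing window bases. Returns min edits.
static int banded_semiglobal(const char* q, int m, const char* w, int n,
                             int band) {
  int width = 2 * band + 1;  // delta = j - i in [0, 2*band]
  std::vector<int> prev(width, DP_INF), cur(width, DP_INF);
  for (int d = 0; d < width; ++d)
    if (d <= n) prev[d] = 0;  // free target prefix
  for (int i = 1; i <= m; ++i) {
    for (int d = 0; d < width; ++d) cur[d] = DP_INF;
    for (int d = 0; d < width; ++d) {
      int j = i + d;
      if (j > n) break;
      int best = DP_INF;
      if (prev[d] < DP_INF && j >= 1) {  // diagonal
        int cost = (q[i - 1] == w[j - 1]) ? 0 : 1;
        best = prev[d] + cost;
      }
      if (d + 1 < width && prev[d + 1] < DP_INF)  // consume query only
        best = std::min(best, prev[d + 1] + 1);
      if (d >= 1 && cur[d - 1] < DP_INF)  // consume window only
        best = std::min(best, cur[d - 1] + 1);
      cur[d] = best;
    }
    std::swap(prev, cur);
  }
  int res = DP_INF;
  for (int d = 0; d < width; ++d)
    if (m + d <= n) res = std::min(res, prev[d]);
  return res;
}

struct Hit {
  int query, target, strand;  // strand +1 / -1
  long long start;
  int dist, clip;
};

static std::string revcomp_str(const char* s, size_t n) {
  std::string r(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = s[n - 1 - i];
    switch (c) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default:  r[i] = 'N';
    }
  }
  return r;
}

static void eval_orientation(const std::string& q, int qi, int strand,
                             const SeedTable& tab, CharacterVector targets,
                             const std::vector<long long>& tlens,
                             int max_edit, int band,
                             std::vector<Hit>& hits) {
  int m = (int)q.size(), k = tab.k;
  if (m < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  // candidate starts per target from exact seed matches at every offset
  std::vector<std::pair<int, long long>> cands;  // (target, inferred start)
  uint64_t fwd = 0;
  int valid = 0;
  for (int i = 0; i < m; ++i) {
    int b = base2bit_se(q[i]);
    if (b < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      int off = i + 1 - k;
      std::vector<uint64_t>::const_iterator lo =
        std::lower_bound(tab.keys.begin(), tab.keys.end(), fwd);
      for (; lo != tab.keys.end() && *lo == fwd; ++lo) {
        uint64_t v = tab.vals[lo - tab.keys.begin()];
        int t = (int)(v >> 40);
        long long p = (long long)(v & ((1ULL << 40) - 1));
        cands.push_back(std::make_pair(t, p - off));
      }
    }
  }
  if (cands.empty()) return;
  std::sort(cands.begin(), cands.end());
  // cluster starts within `band` per target; representative = modal start
  size_t i0 = 0;
  while (i0 < cands.size()) {
    size_t i1 = i0 + 1;
    while (i1 < cands.size() && cands[i1].first == cands[i0].first &&
           cands[i1].second - cands[i1 - 1].second <= band)
      ++i1;
    // modal start in [i0, i1)
    long long best_start = cands[i0].second;
    int best_votes = 0;
    size_t j = i0;
    while (j < i1) {
      size_t j2 = j;
      while (j2 < i1 && cands[j2].second == cands[j].second) ++j2;
      if ((int)(j2 - j) > best_votes) {
        best_votes = (int)(j2 - j);
        best_start = cands[j].second;
      }
      j = j2;
    }
    int t = cands[i0].first;
    long long tlen = tlens[t];
    long long s = best_start;
    long long ws = std::max(0LL, s - band);
    long long we = std::min(tlen, s + m + band);
    int clip = (int)(std::max(0LL, -s) + std::max(0LL, s + m - tlen));
    if (we > ws) {
      const char* tseq = CHAR(STRING_ELT(targets, t));
      int dist = banded_semiglobal(q.c_str(), m, tseq + ws,
                                   (int)(we - ws), band);
      if (dist < DP_INF && dist - clip <= max_edit) {
        Hit h;
        h.query = qi; h.target = t; h.strand = strand;
        h.start = std::max(0LL, s); h.dist = dist; h.clip = clip;
        hits.push_back(h);
      }
    }
    i0 = i1;
  }
}

// Seed-and-extend mapping of queries against targets. Returns every
// candidate placement whose (clip-adjusted) edit distance is <= max_edit.
// Start coordinates are 0-based on the target forward strand.
// [[Rcpp::export]]
DataFrame cpp_map_queries(CharacterVector queries, CharacterVector targets,
                          int seed_len, IntegerVector max_edit, int band) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  if (band < 1) stop("band must be >= 1");
  SeedTable tab;
  build_seed_table(targets, seed_len, tab);
  std::vector<long long> tlens(targets.size());
  for (int t = 0; t < targets.size(); ++t)
    tlens[t] = LENGTH(STRING_ELT(targets, t));

  std::vector<Hit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    const char* qs = CHAR(STRING_ELT(queries, qi));
    size_t qn = LENGTH(STRING_ELT(queries, qi));
    std::string qf(qs, qn);
    std::string qr = revcomp_str(qs, qn);
    int me = max_edit[qi];
    eval_orientation(qf, qi, +1, tab, targets, tlens, me, band, hits);
    eval_orientation(qr, qi, -1, tab, targets, tlens, me, band, hits);
  }

  int n = (int)hits.size();
  IntegerVector query(n), target(n), strand(n), dist(n), clip(n);
  NumericVector start(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].query + 1;
    target[i] = hits[i].target + 1;
    strand[i] = hits[i].strand;
    start[i] = (double)hits[i].start;
    dist[i] = hits[i].dist;
    clip[i] = hits[i].clip;
  }
  return DataFrame::create(_["query"] = query, _["target"] = target,
                           _["strand"] = strand, _["start"] = start,
                           _["dist"] = dist, _["clip"] = clip);
}
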