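#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// Unit-cost Levenshtein distance. 'N' mismatches everything, including 'N'.
static inline bool base_eq(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

static int lev_core(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (base_eq(a[i - 1], b[j - 1]) ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int cpp_levenshtein(std::string a, std::string b) {
  return lev_core(a, b);
}

// All-pairs Levenshtein over a character vector; returns symmetric matrix.
// [[Rcpp::export]]
NumericMatrix cpp_lev_matrix(CharacterVector x) {
  const int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = lev_core(s[i], s[j]);
      d(i, j) = v;
      d(j, i) = v;
    }
  return d;
}

// Levenshtein of one string against each element of a vector.
// [[Rcpp::export]]
IntegerVector cpp_lev_vec(std::string a, CharacterVector b) {
  IntegerVector out(b.size());
  for (int i = 0; i < b.size(); ++i) out[i] = lev_core(a, as<std::string>(b[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Repeat-unit segmentation.
//
// Units follow the telomeric unit convention: a unit begins at a T and runs to
// the base before the next T ("first T ... last non-T base"), and has the
// (T)x(A)y(G)z shape of a canonical-like repeat, i.e. at most one maximal
// G-run. The DP minimises, lexicographically:
//   1. sum of segment edit distances to the canonical unit, plus a large
//      penalty for each boundary NOT at a non-T->T transition and a smaller
//      (but still dominant over edit costs) penalty for each extra maximal
//      G-run inside a segment;
//   2. (tie) maximal number of boundaries at G->T or A->T transitions;
//   3. (tie) fewer segments;
//   4. (tie) leftmost-longest reconstruction.
// Segment lengths are constrained to [minlen, maxlen].
// ---------------------------------------------------------------------------

struct SegBest {
  double cost;
  int good;   // boundaries at G->T or A->T (maximise)
  int nseg;   // minimise
  bool ok;
};

static inline bool seg_better(double c1, int g1, int s1, const SegBest& b) {
  if (!b.ok) return true;
  if (c1 != b.cost) return c1 < b.cost;
  if (g1 != b.good) return g1 > b.good;
  return s1 < b.nseg;
}

static inline bool seg_equal(double c1, int g1, int s1, const SegBest& b) {
  return b.ok && c1 == b.cost && g1 == b.good && s1 == b.nseg;
}

// [[Rcpp::export]]
IntegerVector cpp_tokenize_bounds(std::string seq, std::string pattern,
                                  int minlen, int maxlen) {
  const int n = (int)seq.size();
  const int m = (int)pattern.size();
  if (n < minlen) stop("sequence shorter than the minimum unit length");
  const double P_NT = 1e9;   // boundary not at a non-T->T transition
  const double P_RUN = 1e5;  // each maximal G-run beyond the first in a segment

  // ed[i * (maxlen+1) + l] = edit distance of seq[i, i+l) to pattern
  std::vector<int> ed((size_t)n * (maxlen + 1), 0);
  std::vector<int> col(m + 1), ncol(m + 1);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= m; ++j) col[j] = j;
    int lmax = std::min(maxlen, n - i);
    for (int l = 1; l <= lmax; ++l) {
      ncol[0] = l;
      char c = seq[i + l - 1];
      for (int j = 1; j <= m; ++j) {
        int sub = col[j - 1] + (base_eq(c, pattern[j - 1]) ? 0 : 1);
        int del = col[j] + 1;
        int ins = ncol[j - 1] + 1;
        ncol[j] = std::min(sub, std::min(del, ins));
      }
      std::swap(col, ncol);
      ed[(size_t)i * (maxlen + 1) + l] = col[m];
    }
  }

  // prefix count of maximal-G-run starts
  std::vector<int> gs(n + 1, 0);
  for (int i = 0; i < n; ++i)
    gs[i + 1] = gs[i] + ((seq[i] == 'G' && (i == 0 || seq[i - 1] != 'G')) ? 1 : 0);
  auto extra_runs = [&](int j, int l) {
    int runs = gs[j + l] - gs[j];
    if (seq[j] == 'G' && j > 0 && seq[j - 1] == 'G') runs += 1;
    return runs > 1 ? runs - 1 : 0;
  };
  auto is_trans = [&](int p) {  // boundary before position p
    return seq[p] == 'T' && seq[p - 1] != 'T';
  };
  auto is_good = [&](int p) {
    return seq[p] == 'T' && (seq[p - 1] == 'G' || seq[p - 1] == 'A');
  };

  // suffix DP
  std::vector<SegBest> best(n + 1, {0.0, 0, 0, false});
  best[n] = {0.0, 0, 0, true};
  for (int i = n - 1; i >= 0; --i) {
    int lmax = std::min(maxlen, n - i);
    for (int l = minlen; l <= lmax; ++l) {
      int rest = n - i - l;
      if (rest != 0 && rest < minlen) continue;
      if (!best[i + l].ok) continue;
      double c = ed[(size_t)i * (maxlen + 1) + l] + P_RUN * extra_runs(i, l) +
                 best[i + l].cost;
      int g = best[i + l].good;
      int s = best[i + l].nseg + 1;
      if (i > 0) {
        if (!is_trans(i)) c += P_NT;
        if (is_good(i)) g += 1;
      }
      if (seg_better(c, g, s, best[i])) best[i] = {c, g, s, true};
    }
  }
  if (!best[0].ok) stop("no valid segmentation under unit length constraints");

  // leftmost-longest reconstruction
  std::vector<int> bounds;
  bounds.push_back(0);
  int i = 0;
  while (i < n) {
    int lmax = std::min(maxlen, n - i);
    int pick = -1;
    for (int l = minlen; l <= lmax; ++l) {
      int rest = n - i - l;
      if (rest != 0 && rest < minlen) continue;
      if (!best[i + l].ok) continue;
      double c = ed[(size_t)i * (maxlen + 1) + l] + P_RUN * extra_runs(i, l) +
                 best[i + l].cost;
      int g = best[i + l].good;
      int s = best[i + l].nseg + 1;
      if (i > 0) {
        if (!is_trans(i)) c += P_NT;
        if (is_good(i)) g += 1;
      }
      if (seg_equal(c, g, s, best[i])) pick = l;  // keep largest feasible l
    }
    if (pick < 0) stop("internal error: segmentation reconstruction failed");
    i += pick;
    bounds.push_back(i);
  }

  // unit-convention shift: a boundary sitting after a trailing T of the left
  // segment is moved left so the T opens the next unit, within length bounds
  for (size_t b = 1; b + 1 < bounds.size(); ++b) {
    int p = bounds[b];
    while (p - 1 > bounds[b - 1] && seq[p - 1] == 'T' &&
           (p - bounds[b - 1] - 1) >= minlen &&
           (bounds[b + 1] - (p - 1)) <= maxlen)
      --p;
    bounds[b] = p;
  }
  return wrap(bounds);
}

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) alignment of two integer-coded unit sequences.
// Returns a 2 x L matrix of 1-based indices into a and b; 0 marks a gap.
// Deterministic tie-break: diagonal > consume-a > consume-b (traceback).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_nw_units(IntegerVector a, IntegerVector b,
                           double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = S(i - 1, 0) + gap;
  for (int j = 1; j <= m; ++j) S(0, j) = S(0, j - 1) + gap;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      S(i, j) = std::max(diag, std::max(up, left));
    }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S(i, j) == S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ai.push_back(i); bi.push_back(j); --i; --j;
    } else if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      ai.push_back(i); bi.push_back(0); --i;
    } else {
      ai.push_back(0); bi.push_back(j); --j;
    }
  }
  const int L = (int)ai.size();
  IntegerMatrix out(2, L);
  for (int c = 0; c < L; ++c) {
    out(0, c) = ai[L - 1 - c];
    out(1, c) = bi[L - 1 - c];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Longest exact-match block between each read and one anchor, found by shared
// k-mer seeding and ungapped exact extension. Returns per read:
// block length, 0-based read start, 0-based anchor start.
// ---------------------------------------------------------------------------

static inline int code_base(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_anchor_blocks(std::string anchor, CharacterVector reads, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)anchor.size(); ++i) {
      int c = code_base(anchor[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[h].push_back(i - k + 1);
    }
  }
  const int nr = reads.size();
  IntegerMatrix out(nr, 3);
  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int n = (int)read.size();
    int bestlen = 0, bestrs = -1, bestas = -1;
    uint64_t h = 0; int run = 0;
    int skip_until = -1;
    for (int i = 0; i < n; ++i) {
      int c = code_base(read[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      int rs = i - k + 1;
      if (rs <= skip_until) continue;
      auto it = index.find(h);
      if (it == index.end()) continue;
      for (int as : it->second) {
        int l = rs, a0 = as;
        while (l > 0 && a0 > 0 && read[l - 1] == anchor[a0 - 1] &&
               code_base(read[l - 1]) >= 0) { --l; --a0; }
        int re = rs + k, ae = as + k;
        while (re < n && ae < (int)anchor.size() && read[re] == anchor[ae] &&
               code_base(read[re]) >= 0) { ++re; ++ae; }
        int len = re - l;
        if (len > bestlen) { bestlen = len; bestrs = l; bestas = a0; }
        if (re - k > skip_until) skip_until = re - k;
      }
    }
    out(r, 0) = bestlen;
    out(r, 1) = bestrs;
    out(r, 2) = bestas;
  }
  return out;
}
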