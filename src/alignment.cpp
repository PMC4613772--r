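#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Base codes: A=0 C=1 G=2 T=3 N=4. N never matches anything (including N).
static std::vector<int> encode_dna(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      case 'N': v[i] = 4; break;
      default: stop("sequence contains character outside {A,C,G,T,N}");
    }
  }
  return v;
}

// Optimal global (Needleman-Wunsch) alignment score, linear gap cost.
static double nw_score(const std::vector<int>& a, size_t ai, size_t alen,
                       const std::vector<int>& b, size_t bi, size_t blen,
                       double match, double mismatch, double gap) {
  std::vector<double> prev(blen + 1), cur(blen + 1);
  for (size_t j = 0; j <= blen; ++j) prev[j] = j * gap;
  for (size_t i = 1; i <= alen; ++i) {
    cur[0] = i * gap;
    int ca = a[ai + i - 1];
    for (size_t j = 1; j <= blen; ++j) {
      int cb = b[bi + j - 1];
      double sub = (ca == cb && ca < 4) ? match : mismatch;
      double best = prev[j - 1] + sub;
      double d = prev[j] + gap; if (d > best) best = d;
      double l = cur[j - 1] + gap; if (l > best) best = l;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[blen];
}

// [[Rcpp::export]]
double cpp_window_score(std::string a, std::string b, double match,
                        double mismatch, double gap) {
  if (a.empty() || b.empty()) stop("empty sequence");
  std::vector<int> va = encode_dna(a), vb = encode_dna(b);
  return nw_score(va, 0, va.size(), vb, 0, vb.size(), match, mismatch, gap);
}

// Bit-parallel global Levenshtein distance (Myers/Hyyro) between the length-w
// pattern starting at a[ai] and the length-w text starting at b[bi].
// Under the default scheme (match 1, mismatch 0, gap -0.5) the optimal global
// alignment score of two length-w windows equals w - editdistance: an
// alignment with M matches, X mismatches and G total gap symbols has score
// M - G/2 and corresponds to an edit script of cost X + G, with
// M + X + G/2 = w; eliminating M gives score = w - (X + G).
static inline int myers_dist(const uint64_t* peq, const std::vector<int>& b,
                             size_t bi, int w) {
  const uint64_t hibit = 1ULL << (w - 1);
  uint64_t VP = (w == 64) ? ~0ULL : ((1ULL << w) - 1ULL);
  uint64_t VN = 0;
  int dist = w;
  for (int j = 0; j < w; ++j) {
    uint64_t Eq = peq[b[bi + j]];
    uint64_t D0 = (((Eq & VP) + VP) ^ VP) | Eq | VN;
    uint64_t HP = VN | ~(D0 | VP);
    uint64_t HN = VP & D0;
    if (HP & hibit) ++dist;
    else if (HN & hibit) --dist;
    HP = (HP << 1) | 1ULL;
    HN = HN << 1;
    VP = HN | ~(D0 | HP);
    VN = HP & D0;
  }
  return dist;
}

static bool is_default_scheme(double match, double mismatch, double gap, int w) {
  return match == 1.0 && mismatch == 0.0 && gap == -0.5 && w <= 64;
}

static void build_peq(uint64_t* peq, const std::vector<int>& a, size_t ai, int w) {
  for (int c = 0; c < 5; ++c) peq[c] = 0;
  for (int k = 0; k < w; ++k) {
    int c = a[ai + k];
    if (c < 4) peq[c] |= (1ULL << k);  // N rows match nothing
  }
}

// Score grid for every pair of w-length windows (rows: s1 offsets, cols: s2
// offsets). Equals cpp_window_score on each window pair.
// [[Rcpp::export]]
NumericMatrix cpp_all_window_pairs(std::string s1, std::string s2, int w,
                                   double match, double mismatch, double gap) {
  if (w < 1) stop("window length must be >= 1");
  std::vector<int> a = encode_dna(s1), b = encode_dna(s2);
  if ((int)a.size() < w || (int)b.size() < w)
    stop("sequence shorter than window length");
  int m = a.size() - w + 1, n = b.size() - w + 1;
  NumericMatrix out(m, n);
  if (is_default_scheme(match, mismatch, gap, w)) {
    uint64_t peq[5];
    for (int i = 0; i < m; ++i) {
      build_peq(peq, a, i, w);
      for (int j = 0; j < n; ++j)
        out(i, j) = (double)w - myers_dist(peq, b, j, w);
    }
  } else {
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j)
        out(i, j) = nw_score(a, i, w, b, j, w, match, mismatch, gap);
  }
  return out;
}

// Sparse variant: only window pairs with score >= min_raw, as 0-based offset
// triplets. Identical scores to cpp_all_window_pairs.
// [[Rcpp::export]]
DataFrame cpp_significant_window_pairs(std::string s1, std::string s2, int w,
                                       double match, double mismatch,
                                       double gap, double min_raw) {
  if (w < 1) stop("window length must be >= 1");
  std::vector<int> a = encode_dna(s1), b = encode_dna(s2);
  if ((int)a.size() < w || (int)b.size() < w)
    stop("sequence shorter than window length");
  int m = a.size() - w + 1, n = b.size() - w + 1;
  std::vector<int> ii, jj;
  std::vector<double> sc;
  bool fast = is_default_scheme(match, mismatch, gap, w);
  uint64_t peq[5];
  for (int i = 0; i < m; ++i) {
    if (fast) build_peq(peq, a, i, w);
    for (int j = 0; j < n; ++j) {
      double s = fast ? ((double)w - myers_dist(peq, b, j, w))
                      : nw_score(a, i, w, b, j, w, match, mismatch, gap);
      if (s >= min_raw) {
        ii.push_back(i); jj.push_back(j); sc.push_back(s);
      }
    }
  }
  return DataFrame::create(_["central_offset"] = ii,
                           _["comparator_offset"] = jj,
                           _["raw_score"] = sc);
}
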