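#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// RNA codes: A=0 C=1 G=2 U=3 N=4 gap=5. Watson-Crick plus GU wobble.
static inline bool pairable(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}

// Maximum number of base pairs (Nussinov), min hairpin loop length minloop.
// [[Rcpp::export]]
int cpp_max_pairs(IntegerVector codes, int minloop) {
  int n = codes.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> N((size_t)n * n, 0);
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[(size_t)(i + 1) * n + j];  // i unpaired
      for (int k = i + minloop + 1; k <= j; ++k) {
        if (!pairable(codes[i], codes[k])) continue;
        int inner = (k - i >= 2) ? N[(size_t)(i + 1) * n + (k - 1)] : 0;
        int right = (k + 1 <= j) ? N[(size_t)(k + 1) * n + j] : 0;
        int v = 1 + inner + right;
        if (v > best) best = v;
      }
      N[(size_t)i * n + j] = best;
    }
  }
  return N[(size_t)0 * n + (n - 1)];
}

// Weighted consensus variant: weight(i,j) = number of alignment rows whose
// residues at columns i and j can pair. Maximizes the total weight; returns
// the integer total (divide by row count for the mean-fraction energy).
// [[Rcpp::export]]
int cpp_max_consensus_weight(IntegerMatrix block, int minloop) {
  int nr = block.nrow(), n = block.ncol();
  if (n == 0 || nr == 0) stop("empty alignment");
  // precompute pair weights
  std::vector<int> wgt((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + minloop + 1; j < n; ++j) {
      int c = 0;
      for (int r = 0; r < nr; ++r)
        if (pairable(block(r, i), block(r, j))) ++c;
      wgt[(size_t)i * n + j] = c;
    }
  std::vector<int> N((size_t)n * n, 0);
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[(size_t)(i + 1) * n + j];
      for (int k = i + minloop + 1; k <= j; ++k) {
        int wik = wgt[(size_t)i * n + k];
        if (wik <= 0) continue;
        int inner = (k - i >= 2) ? N[(size_t)(i + 1) * n + (k - 1)] : 0;
        int right = (k + 1 <= j) ? N[(size_t)(k + 1) * n + j] : 0;
        int v = wik + inner + right;
        if (v > best) best = v;
      }
      N[(size_t)i * n + j] = best;
    }
  }
  return N[(size_t)0 * n + (n - 1)];
}

// Structure traceback shared by the plain and consensus folders. Candidate
// structures are ranked by (score desc, pair count asc, dot-bracket string
// lexicographically asc); the decomposition by the role of the leftmost
// position enumerates every secondary structure exactly once, so the memoized
// per-interval optimum composes into the global optimum.
struct Cell { long score; int pairs; std::string s; bool done; };

class Tracer {
public:
  int n, minloop;
  std::vector<long> wgt;  // weight of pair (i,j); <=0 means not allowed
  std::vector<Cell> memo;
  Tracer(int n_, int minloop_) : n(n_), minloop(minloop_),
    wgt((size_t)n_ * n_, 0), memo((size_t)n_ * n_) {
    for (auto& c : memo) c.done = false;
  }
  const Cell& solve(int i, int j) {
    static Cell empty{0, 0, "", true};
    if (i > j) return empty;
    Cell& c = memo[(size_t)i * n + j];
    if (c.done) return c;
    const Cell& rest = solve(i + 1, j);
    c.score = rest.score; c.pairs = rest.pairs; c.s = "." + rest.s;
    for (int k = i + minloop + 1; k <= j; ++k) {
      long wik = wgt[(size_t)i * n + k];
      if (wik <= 0) continue;
      const Cell& inner = solve(i + 1, k - 1);
      const Cell& right = solve(k + 1, j);
      long sc = wik + inner.score + right.score;
      int np = 1 + inner.pairs + right.pairs;
      if (sc < c.score) continue;
      if (sc == c.score && np > c.pairs) continue;
      std::string cand = "(" + inner.s + ")" + right.s;
      if (sc == c.score && np == c.pairs && cand >= c.s) continue;
      c.score = sc; c.pairs = np; c.s = cand;
    }
    c.done = true;
    return c;
  }
};

// [[Rcpp::export]]
List cpp_fold_structure(IntegerVector codes, int minloop) {
  int n = codes.size();
  if (n == 0) stop("empty sequence");
  Tracer tr(n, minloop);
  for (int i = 0; i < n; ++i)
    for (int k = i + minloop + 1; k < n; ++k)
      tr.wgt[(size_t)i * n + k] = pairable(codes[i], codes[k]) ? 1 : 0;
  const Cell& c = tr.solve(0, n - 1);
  return List::create(_["structure"] = c.s, _["pairs"] = c.pairs,
                      _["score"] = (double)c.score);
}

// [[Rcpp::export]]
List cpp_consensus_structure(IntegerMatrix block, int minloop) {
  int nr = block.nrow(), n = block.ncol();
  if (n == 0 || nr == 0) stop("empty alignment");
  Tracer tr(n, minloop);
  for (int i = 0; i < n; ++i)
    for (int k = i + minloop + 1; k < n; ++k) {
      int c = 0;
      for (int r = 0; r < nr; ++r)
        if (pairable(block(r, i), block(r, k))) ++c;
      tr.wgt[(size_t)i * n + k] = c;
    }
  const Cell& c = tr.solve(0, n - 1);
  return List::create(_["structure"] = c.s, _["pairs"] = c.pairs,
                      _["score"] = (double)c.score);
}
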