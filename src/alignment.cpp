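#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch 0, linear
// gap -1. End gaps are penalized. Among co-optimal alignments the one
// maximizing (score, identical pairs, aligned non-gap columns)
// lexicographically is taken, so the reported identity is canonical.
// Lexicographic DP is exact here because all three objectives are
// additive along a path and any two prefixes reaching the same cell are
// extended by identical suffix contributions.
//
// identity = identical pairs / alignment length,
// alignment length = len(a) + len(b) - aligned pairs.
// [[Rcpp::export(name = ".align_stats")]]
List align_stats(std::string a, std::string b) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");

  const int W = m + 1;
  std::vector<int> S((n + 1) * W), Ma((n + 1) * W), P((n + 1) * W);

  for (int j = 0; j <= m; ++j) { S[j] = -j; Ma[j] = 0; P[j] = 0; }
  for (int i = 1; i <= n; ++i) { S[i * W] = -i; Ma[i * W] = 0; P[i * W] = 0; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      const bool eq = a[i - 1] == b[j - 1];
      // diagonal candidate
      int bs = S[d] + (eq ? 1 : 0), bm = Ma[d] + (eq ? 1 : 0), bp = P[d] + 1;
      // up (gap in b)
      int cs = S[u] - 1, cm = Ma[u], cp = P[u];
      if (cs > bs || (cs == bs && (cm > bm || (cm == bm && cp > bp)))) {
        bs = cs; bm = cm; bp = cp;
      }
      // left (gap in a)
      cs = S[l] - 1; cm = Ma[l]; cp = P[l];
      if (cs > bs || (cs == bs && (cm > bm || (cm == bm && cp > bp)))) {
        bs = cs; bm = cm; bp = cp;
      }
      S[c] = bs; Ma[c] = bm; P[c] = bp;
    }
  }

  const int c = n * W + m;
  const int alen = n + m - P[c];
  return List::create(
    _["identity"] = (double) Ma[c] / (double) alen,
    _["score"] = S[c],
    _["matches"] = Ma[c],
    _["aligned_pairs"] = P[c],
    _["alignment_length"] = alen,
    _["coverage_a"] = (double) P[c] / (double) n,
    _["coverage_b"] = (double) P[c] / (double) m);
}
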