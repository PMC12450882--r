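#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Weighted running-sum enrichment score from sorted 0-based hit positions.
// absw: |stat|^q in rank order. Extremum candidates occur just before or
// just after each hit; ties between the positive and negative deviation
// resolve to the positive one.
static double es_from_positions(const NumericVector& absw,
                                const std::vector<int>& pos) {
  const int N = absw.size();
  const int k = (int)pos.size();
  double sumw = 0.0;
  for (int i = 0; i < k; ++i) sumw += absw[pos[i]];
  if (k == N) return 1.0;  // no misses: the sum reaches 1 at the end
  const double miss = 1.0 / (double)(N - k);
  double cw = 0.0, best_pos = 0.0, best_neg = 0.0;
  for (int i = 0; i < k; ++i) {
    double w = (sumw > 0.0) ? absw[pos[i]] / sumw : 1.0 / (double)k;
    double drop = (double)(pos[i] - i) * miss;
    double before = cw - drop;
    cw += w;
    double after = cw - drop;
    if (after > best_pos) best_pos = after;
    if (before < best_neg) best_neg = before;
  }
  return (best_pos >= -best_neg) ? best_pos : best_neg;
}

// Null enrichment scores by gene-set permutation, one column per set size.
// Random same-size position sets are drawn with a partial Fisher-Yates
// shuffle using R's RNG, so results follow set.seed().
// [[Rcpp::export(name = "es_null_cpp")]]
NumericMatrix es_null_cpp(NumericVector absw, IntegerVector sizes, int B) {
  const int N = absw.size();
  NumericMatrix out(B, sizes.size());
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  std::vector<int> pos;
  for (int j = 0; j < sizes.size(); ++j) {
    const int k = sizes[j];
    if (k < 1 || k > N) stop("set size out of range");
    pos.resize(k);
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < k; ++i) {
        int r = i + (int)(unif_rand() * (double)(N - i));
        if (r >= N) r = N - 1;
        std::swap(perm[i], perm[r]);
        pos[i] = perm[i];
      }
      std::sort(pos.begin(), pos.end());
      out(b, j) = es_from_positions(absw, pos);
    }
  }
  return out;
}
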