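#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact bottom-up solution of the recursive diversity value
//   U(S) = max_{i in S} { U(S \ i) + min_{j in S \ i} d(i, j) },  U({i}) = 0
// over all 2^K subsets, with backtracking of the argmax chain.
//
// `pref` gives the order in which elements are scanned for the argmax
// (0-based indices in ascending label order), so exact ties resolve to the
// lexicographically smallest label. Memory is O(2^K) doubles plus one byte
// per subset for the backtrack table.

// [[Rcpp::export]]
List weitzman_dp_cpp(NumericMatrix d, IntegerVector pref) {
  const int K = d.nrow();
  if (d.ncol() != K) stop("distance matrix must be square");
  if (K < 1) stop("at least one element required");
  if (K > 25) stop("subset dynamic program is limited to 25 elements");

  const size_t n = (size_t)1 << K;
  std::vector<double> U(n, 0.0);
  std::vector<signed char> choice(n, -1);

  for (size_t mask = 3; mask < n; ++mask) {
    if (__builtin_popcountll(mask) < 2) continue;
    double best = -1.0;
    int besti = -1;
    for (int t = 0; t < K; ++t) {
      const int i = pref[t];
      if (!((mask >> i) & 1)) continue;
      const size_t rest = mask & ~((size_t)1 << i);
      double mind = R_PosInf;
      for (int j = 0; j < K; ++j) {
        if ((rest >> j) & 1) {
          const double v = d(i, j);
          if (v < mind) mind = v;
        }
      }
      const double val = U[rest] + mind;
      if (val > best) { best = val; besti = i; }
    }
    U[mask] = best;
    choice[mask] = (signed char)besti;
  }

  std::vector<int> order;
  std::vector<double> inc;
  size_t mask = n - 1;
  while (__builtin_popcountll(mask) > 1) {
    const int i = choice[mask];
    const size_t rest = mask & ~((size_t)1 << i);
    double mind = R_PosInf;
    for (int j = 0; j < K; ++j) {
      if ((rest >> j) & 1) {
        const double v = d(i, j);
        if (v < mind) mind = v;
      }
    }
    order.push_back(i + 1);
    inc.push_back(mind);
    mask = rest;
  }
  int survivor = 0;
  for (int j = 0; j < K; ++j) if ((mask >> j) & 1) survivor = j + 1;

  return List::create(_["value"] = U[n - 1],
                      _["order"] = wrap(order),
                      _["increments"] = wrap(inc),
                      _["survivor"] = survivor);
}
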