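#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact two-sided permutation p-value for Spearman's rho with average ranks.
//
// For fixed marginal ranks, rho is a strictly increasing function of
// S = sum_i rx_i * ry_i, so the two-sided tail on rho equals the tail on
// |S - E[S]| where E[S] = sum(rx) * sum(ry) / n under uniform permutation.
// Distinct multiset permutations of tied ranks are equiprobable, so
// enumerating them with std::next_permutation (which visits each distinct
// arrangement exactly once from the sorted start) is exact.
//
// Feasible for n <= 10 (10! = 3.6e6 arrangements at most).
// [[Rcpp::export(name = ".spearmanPermPvalue")]]
double spearmanPermPvalue(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) stop("rank vectors must have equal length");
  if (n > 10) stop("exact permutation p restricted to n <= 10");
  std::vector<double> y(ry.begin(), ry.end());
  std::sort(y.begin(), y.end());
  double sx = 0.0, sy = 0.0, sObs = 0.0;
  for (int i = 0; i < n; ++i) {
    sx += rx[i];
    sy += ry[i];
    sObs += rx[i] * ry[i];
  }
  const double mu = sx * sy / n;
  // ranks are multiples of 1/2, so S moves in steps of >= 1/4; a 1e-9
  // cushion absorbs floating-point noise without admitting smaller |S - mu|
  const double dObs = std::fabs(sObs - mu) - 1e-9;
  double total = 0.0, hits = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * y[i];
    total += 1.0;
    if (std::fabs(s - mu) >= dObs) hits += 1.0;
  } while (std::next_permutation(y.begin(), y.end()));
  return hits / total;
}
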