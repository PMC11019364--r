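#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal two-sample arc statistic for circular binary segmentation.
//
// For an arc of k consecutive values starting after index i (0-based,
// half-open [i, i+k)), the statistic is
//   |mean(arc) - mean(rest)| / sqrt(1/k + 1/(n-k)),
// i.e. the numerator of the two-sample t statistic with the (permutation-
// invariant) scale factor dropped. Arcs are constrained so that the arc and
// each non-empty flanking piece contain at least min_width values.
//
// lengths: the arc lengths to scan (all valid lengths for an exact scan, a
// geometric grid for long series). Returns the best statistic and its arc
// bounds; when stop_above > 0, returns early as soon as any arc exceeds it
// (used inside the permutation loop, where only exceedance matters).
// [[Rcpp::export]]
List max_arc_stat_cpp(NumericVector x, IntegerVector lengths, int min_width,
                      double stop_above = -1.0) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int li = 0; li < lengths.size(); ++li) {
    int k = lengths[li];
    if (k < min_width || k > n - min_width) continue;
    double w = 1.0 / std::sqrt(1.0 / k + 1.0 / (double)(n - k));
    double tot = S[n];
    for (int i = 0; i + k <= n; ++i) {
      int left = i, right = n - i - k;
      if (left != 0 && left < min_width) continue;
      if (right != 0 && right < min_width) continue;
      double in = S[i + k] - S[i];
      double stat = std::fabs(in / k - (tot - in) / (n - k)) * w;
      if (stat > best) {
        best = stat;
        bi = i;
        bj = i + k;
        if (stop_above > 0 && best >= stop_above) {
          return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
        }
      }
    }
  }
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}
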