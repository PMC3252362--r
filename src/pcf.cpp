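#include <Rcpp.h>
#include <cmath>
#include "torus.h"

using namespace Rcpp;

// Ordered-pair counts per distance interval (r_k, r_{k+1}], r_k = k L / Mg.
// If same_set, the two coordinate sets are identical and self-pairs are
// excluded (each unordered pair contributes two ordered pairs).  Otherwise
// counts pairs (m in set 1, n in set 2).
// [[Rcpp::export]]
NumericVector pair_count_bins_cpp(NumericVector x1, NumericVector y1,
                                  NumericVector x2, NumericVector y2,
                                  double L, int Mg, bool same_set) {
    const double w = L / Mg;
    NumericVector counts(Mg);
    const int n1 = x1.size(), n2 = x2.size();
    if (same_set) {
        for (int i = 0; i < n1; ++i)
            for (int j = i + 1; j < n1; ++j) {
                double d = torus_dist(x1[i], y1[i], x1[j], y1[j], L);
                if (d <= 0.0) continue;
                int k = (int)std::ceil(d / w) - 1;
                if (k >= 0 && k < Mg) counts[k] += 2.0;
            }
    } else {
        for (int i = 0; i < n1; ++i)
            for (int j = 0; j < n2; ++j) {
                double d = torus_dist(x1[i], y1[i], x2[j], y2[j], L);
                if (d <= 0.0) continue;
                int k = (int)std::ceil(d / w) - 1;
                if (k >= 0 && k < Mg) counts[k] += 1.0;
            }
    }
    return counts;
}
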