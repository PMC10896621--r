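// Joint spatial/range (bilateral) filter for depth maps. Invalid pixels
// (NaN) are ignored as neighbours and stay invalid in the output, so the
// silhouette is untouched; the range kernel prevents averaging across
// depth discontinuities.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".bilateral_depth")]]
NumericMatrix bilateral_depth(NumericMatrix d, int radius, double sigma_s,
                              double sigma_r) {
  int nr = d.nrow(), nc = d.ncol();
  NumericMatrix out(nr, nc);
  double inv2ss = 1.0 / (2.0 * sigma_s * sigma_s);
  double inv2sr = 1.0 / (2.0 * sigma_r * sigma_r);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double center = d(i, j);
      if (!std::isfinite(center)) {
        out(i, j) = NA_REAL;
        continue;
      }
      double num = 0, den = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -radius; di <= radius; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          double v = d(ii, jj);
          if (!std::isfinite(v)) continue;
          double dz = v - center;
          double w = std::exp(-(di * di + dj * dj) * inv2ss - dz * dz * inv2sr);
          num += w * v;
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}
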