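#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Basic 2D non-local means: search window radius `search`, patch radius
// `patch`, bandwidth h in intensity units. Replicate padding at borders.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_2d(NumericMatrix img, double h, int search,
                             int patch) {
  const int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(nx, ny);
  const double h2 = h * h;
  auto px = [&](int i, int j) {
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    return img(i, j);
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double wsum = 0.0, acc = 0.0;
      for (int dj = -search; dj <= search; ++dj)
        for (int di = -search; di <= search; ++di) {
          double d2 = 0.0;
          int npx = 0;
          for (int pj = -patch; pj <= patch; ++pj)
            for (int pi = -patch; pi <= patch; ++pi) {
              double d = px(i + pi, j + pj) - px(i + di + pi, j + dj + pj);
              d2 += d * d;
              ++npx;
            }
          double w = std::exp(-(d2 / npx) / h2);
          wsum += w;
          acc += w * px(i + di, j + dj);
        }
      out(i, j) = acc / wsum;
    }
  return out;
}
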