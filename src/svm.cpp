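#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// C-SVC trained by SMO with maximal-violating-pair working-set selection.
// kernel: 0 = linear, 1 = RBF exp(-gamma * ||u - v||^2).

namespace {

inline double kern(const NumericMatrix &X, int i, int j, int kernel,
                   double gamma) {
  const int d = X.ncol();
  if (kernel == 0) {
    double s = 0;
    for (int k = 0; k < d; ++k) s += X(i, k) * X(j, k);
    return s;
  }
  double s = 0;
  for (int k = 0; k < d; ++k) {
    double df = X(i, k) - X(j, k);
    s += df * df;
  }
  return std::exp(-gamma * s);
}

} // namespace

// [[Rcpp::export]]
List svm_train_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                   int kernel, double eps, int max_iter) {
  const int n = X.nrow();
  std::vector<std::vector<float> > K(n, std::vector<float>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[i][j] = K[j][i] = (float)kern(X, i, j, kernel, gamma);

  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  int iter = 0;
  double m = 0, M = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    int ii = -1, jj = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = y[t] - f[t];          // -E_t
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > m) { m = v; ii = t; }
      if (lo && v < M) { M = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || m - M < eps) break;

    const int i = ii, j = jj;
    double eta = (double)K[i][i] + K[j][j] - 2.0 * K[i][j];
    if (eta <= 0) eta = 1e-12;
    double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double aj_old = alpha[j], ai_old = alpha[i];
    double aj = aj_old + y[j] * (Ei - Ej) / eta;
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (aj > H) aj = H; else if (aj < L) aj = L;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    if (std::fabs(di) < 1e-15 && std::fabs(dj) < 1e-15) break;
    alpha[i] = ai; alpha[j] = aj;
    for (int t = 0; t < n; ++t) f[t] += di * K[i][t] + dj * K[j][t];
  }

  // intercept from free support vectors, else the KKT midpoint
  double bsum = 0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      bsum += y[t] - f[t];
      ++nfree;
    }
  double b = nfree > 0 ? bsum / nfree : (m + M) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}

// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix Xsv, NumericVector coef, double b,
                               double gamma, int kernel, NumericMatrix Xnew) {
  const int nsv = Xsv.nrow(), n = Xnew.nrow(), d = Xsv.ncol();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double s = b;
    for (int t = 0; t < nsv; ++t) {
      double k;
      if (kernel == 0) {
        k = 0;
        for (int c = 0; c < d; ++c) k += Xsv(t, c) * Xnew(q, c);
      } else {
        double ss = 0;
        for (int c = 0; c < d; ++c) {
          double df = Xsv(t, c) - Xnew(q, c);
          ss += df * df;
        }
        k = std::exp(-gamma * ss);
      }
      s += coef[t] * k;
    }
    out[q] = s;
  }
  return out;
}
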