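#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-pixel GLCM texture maps.
//
// levels: integer array (nx*ny*nz, NA = invalid pixel), values in [0, G-1].
// offsets: k x 3 integer matrix of distance-1 direction vectors; each offset
// is accumulated symmetrically (both orderings of every pair).
// win: window radius per axis (Chebyshev box around the center pixel).
// Features are computed per direction from the normalized window GLCM and
// averaged over the directions that produced at least one pair.

static const int N_FEAT = 13;

namespace {

struct Accum {
  int G;
  std::vector<double> joint;   // G*G
  std::vector<double> psum;    // 2G-1, index i+j
  std::vector<double> pdiff;   // G,    index |i-j|
  std::vector<int> tj, ts, td; // touched indices
  double total;
  Accum(int G_) : G(G_), joint(G_ * G_, 0.0), psum(2 * G_ - 1, 0.0),
                  pdiff(G_, 0.0), total(0.0) {}
  inline void add(int i, int j) {
    int a = i * G + j, b = j * G + i;
    if (a == b) {                   // ordered pair and its reverse coincide
      if (joint[a] == 0.0) tj.push_back(a);
      joint[a] += 2.0;
    } else {
      if (joint[a] == 0.0) tj.push_back(a);
      joint[a] += 1.0;
      if (joint[b] == 0.0) tj.push_back(b);
      joint[b] += 1.0;
    }
    int s = i + j;
    if (psum[s] == 0.0) ts.push_back(s);
    psum[s] += 2.0;
    int d = std::abs(i - j);
    if (pdiff[d] == 0.0) td.push_back(d);
    pdiff[d] += 2.0;
    total += 2.0;
  }
  inline void reset() {
    for (int a : tj) joint[a] = 0.0;
    for (int s : ts) psum[s] = 0.0;
    for (int d : td) pdiff[d] = 0.0;
    tj.clear(); ts.clear(); td.clear();
    total = 0.0;
  }
};

// 13 Haralick features from the accumulated (unnormalized) counts.
void features_from_accum(const Accum &ac, double *f) {
  const double tot = ac.total;
  double energy = 0, contrast = 0, entropy = 0, homog = 0, dissim = 0,
         autoc = 0, mux = 0, muy = 0;
  for (int a : ac.tj) {
    int i = a / ac.G, j = a % ac.G;
    double p = ac.joint[a] / tot;
    energy += p * p;
    double dij = (double)(i - j);
    contrast += dij * dij * p;
    entropy -= p * std::log2(p);
    homog += p / (1.0 + dij * dij);
    dissim += std::fabs(dij) * p;
    autoc += (double)i * (double)j * p;
    mux += i * p;
    muy += j * p;
  }
  double sx2 = 0, sy2 = 0, clus = 0, jointvar = 0;
  for (int a : ac.tj) {
    int i = a / ac.G, j = a % ac.G;
    double p = ac.joint[a] / tot;
    sx2 += (i - mux) * (i - mux) * p;
    sy2 += (j - muy) * (j - muy) * p;
    double c = (i + j - mux - muy);
    clus += c * c * p;
    jointvar += (i - mux) * (i - mux) * p;  // mu of the joint index distribution
  }
  double corr = 0.0;
  double sxsy = std::sqrt(sx2) * std::sqrt(sy2);
  if (sxsy > 0) corr = (autoc - mux * muy) / sxsy;
  double sum_avg = 0, sum_ent = 0;
  for (int s : ac.ts) {
    double p = ac.psum[s] / tot;
    sum_avg += s * p;
    sum_ent -= p * std::log2(p);
  }
  double mud = 0, diff_ent = 0;
  for (int d : ac.td) {
    double p = ac.pdiff[d] / tot;
    mud += d * p;
    diff_ent -= p * std::log2(p);
  }
  double diff_var = 0;
  for (int d : ac.td) {
    double p = ac.pdiff[d] / tot;
    diff_var += (d - mud) * (d - mud) * p;
  }
  f[0] = energy;   f[1] = contrast; f[2] = entropy;  f[3] = homog;
  f[4] = dissim;   f[5] = corr;     f[6] = jointvar; f[7] = sum_avg;
  f[8] = sum_ent;  f[9] = diff_var; f[10] = diff_ent;
  f[11] = autoc;   f[12] = clus;
}

} // namespace

// [[Rcpp::export]]
List texture_map_cpp(IntegerVector levels, IntegerVector dims, int G,
                     IntegerVector win, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const int wx = win[0], wy = win[1], wz = win.size() > 2 ? win[2] : 0;
  const int nOff = offsets.nrow();
  auto at = [&](int x, int y, int z) { return x + nx * (y + ny * z); };

  std::vector<NumericVector> maps;
  for (int k = 0; k < N_FEAT; ++k)
    maps.push_back(NumericVector(levels.size(), NA_REAL));
  LogicalVector valid(levels.size(), false);

  Accum ac(G);
  std::vector<double> fdir(N_FEAT), facc(N_FEAT);

  for (int z = 0; z < nz; ++z)
   for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      if (levels[at(x, y, z)] == NA_INTEGER) continue;
      int nDirWithPairs = 0;
      std::fill(facc.begin(), facc.end(), 0.0);
      for (int o = 0; o < nOff; ++o) {
        const int dx = offsets(o, 0), dy = offsets(o, 1),
                  dz = offsets.ncol() > 2 ? offsets(o, 2) : 0;
        ac.reset();
        const int x0 = std::max(0, x - wx), x1 = std::min(nx - 1, x + wx);
        const int y0 = std::max(0, y - wy), y1 = std::min(ny - 1, y + wy);
        const int z0 = std::max(0, z - wz), z1 = std::min(nz - 1, z + wz);
        for (int c = z0; c <= z1; ++c)
         for (int b = y0; b <= y1; ++b)
          for (int a = x0; a <= x1; ++a) {
            int la = levels[at(a, b, c)];
            if (la == NA_INTEGER) continue;
            int a2 = a + dx, b2 = b + dy, c2 = c + dz;
            if (a2 < x0 || a2 > x1 || b2 < y0 || b2 > y1 ||
                c2 < z0 || c2 > z1) continue;
            int lb = levels[at(a2, b2, c2)];
            if (lb == NA_INTEGER) continue;
            ac.add(la, lb);
          }
        if (ac.total > 0) {
          features_from_accum(ac, fdir.data());
          for (int k = 0; k < N_FEAT; ++k) facc[k] += fdir[k];
          ++nDirWithPairs;
        }
      }
      if (nDirWithPairs > 0) {
        valid[at(x, y, z)] = true;
        for (int k = 0; k < N_FEAT; ++k)
          maps[k][at(x, y, z)] = facc[k] / nDirWithPairs;
      }
    }
  ac.reset();
  List out(N_FEAT + 1);
  for (int k = 0; k < N_FEAT; ++k) out[k] = maps[k];
  out[N_FEAT] = valid;
  return out;
}
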