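#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas), with grid
// spacing `sp` so distances come out in physical units.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double sp) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = R_NegInf; zb[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * sp, xv = v[k] * sp;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * sp;
    while (zb[k + 1] < xq) ++k;
    double dx = xq - v[k] * sp;
    d[q] = dx * dx + f[v[k]];
  }
}

// Anisotropic squared Euclidean distance transform: for every voxel, the
// squared physical distance (µm²) to the nearest voxel where feature != 0.
// [[Rcpp::export]]
NumericVector cc_edt_sq(LogicalVector feature, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite "infinity" keeps the parabola intersections well defined
  // in rows that contain no feature voxel
  const double BIG = 1e30;
  NumericVector d(feature.size());
  for (R_xlen_t i = 0; i < feature.size(); ++i)
    d[i] = feature[i] ? 0.0 : BIG;

  std::vector<double> f, g;
  // x pass
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, g, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // y pass
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[x + nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, g, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[x + nx * (y + (R_xlen_t)ny * z)] = g[y];
    }
  // z pass
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[x + nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, g, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) d[x + nx * (y + (R_xlen_t)ny * z)] = g[z];
    }
  return d;
}
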