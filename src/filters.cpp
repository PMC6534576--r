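#include <Rcpp.h>
using namespace Rcpp;

// Volumes are R arrays with dim (nx, ny, nz), column-major:
// linear index = x + nx * (y + ny * z), 0-based here.

static inline int reflect(int i, int n) {
  // reflect-101 boundary (a b c | b a), degenerate n == 1 -> 0
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Separable convolution along one axis (0 = x, 1 = y, 2 = z) with a centred
// odd-length kernel; reflective boundary.
// [[Rcpp::export]]
NumericVector cc_convolve_axis(NumericVector vol, IntegerVector dim,
                               NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int k = kernel.size();
  if (k % 2 == 0) stop("kernel length must be odd");
  const int h = k / 2;
  NumericVector out(vol.size());
  const int n_axis = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        const int pos = (axis == 0) ? x : (axis == 1) ? y : z;
        for (int j = -h; j <= h; ++j) {
          int p = reflect(pos + j, n_axis);
          int xi = x, yi = y, zi = z;
          if (axis == 0) xi = p; else if (axis == 1) yi = p; else zi = p;
          acc += kernel[j + h] * vol[xi + nx * (yi + (R_xlen_t)ny * zi)];
        }
        out[x + nx * (y + (R_xlen_t)ny * z)] = acc;
      }
    }
  }
  return out;
}

// Local maxima within an axis-aligned ellipsoidal neighbourhood of voxel
// radii (rx, ry, rz). A voxel is a maximum if it is >= every neighbour in the
// neighbourhood and strictly > at least one (constant plateaus excluded).
// [[Rcpp::export]]
LogicalVector cc_local_max(NumericVector vol, IntegerVector dim,
                           int rx, int ry, int rz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double v = vol[x + nx * (y + (R_xlen_t)ny * z)];
        bool is_max = true, strict = false;
        for (int dz = -rz; dz <= rz && is_max; ++dz)
          for (int dy = -ry; dy <= ry && is_max; ++dy)
            for (int dx = -rx; dx <= rx && is_max; ++dx) {
              if (!dx && !dy && !dz) continue;
              double e = (rx ? (double)dx * dx / (rx * rx) : 0) +
                         (ry ? (double)dy * dy / (ry * ry) : 0) +
                         (rz ? (double)dz * dz / (rz * rz) : 0);
              if (e > 1.0) continue;
              int xi = x + dx, yi = y + dy, zi = z + dz;
              if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
                continue;
              double w = vol[xi + nx * (yi + (R_xlen_t)ny * zi)];
              if (w > v) is_max = false;
              else if (w < v) strict = true;
            }
        out[x + nx * (y + (R_xlen_t)ny * z)] = is_max && strict;
      }
  return out;
}
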