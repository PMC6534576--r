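#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// Grayscale erosion (min) or dilation (max) over an arbitrary structuring
// element given as an N x 3 matrix of voxel offsets (dx, dy, dz).
// Boundary: replicate nearest voxel (appropriate for background estimation).
// [[Rcpp::export]]
NumericVector cc_gray_morph(NumericVector vol, IntegerVector dim,
                            IntegerMatrix offsets, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = offsets.nrow();
  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double best = dilate ? R_NegInf : R_PosInf;
        for (int j = 0; j < m; ++j) {
          int xi = clampi(x + offsets(j, 0), nx);
          int yi = clampi(y + offsets(j, 1), ny);
          int zi = clampi(z + offsets(j, 2), nz);
          double v = vol[xi + nx * (yi + (R_xlen_t)ny * zi)];
          if (dilate ? (v > best) : (v < best)) best = v;
        }
        out[x + nx * (y + (R_xlen_t)ny * z)] = best;
      }
  return out;
}

// 3D connected-component labelling (6 or 26 connectivity), BFS.
// Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
              continue;
            int xi = x + dx, yi = y + dy, zi = z + dz;
            if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
              continue;
            int idx = xi + nx * (yi + ny * zi);
            if (mask[idx] && !lab[idx]) { lab[idx] = next; q.push(idx); }
          }
    }
  }
  return lab;
}
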