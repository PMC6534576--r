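#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double seg_dist2(double px, double py, double pz,
                               double x1, double y1, double z1,
                               double x2, double y2, double z2) {
  double vx = x2 - x1, vy = y2 - y1, vz = z2 - z1;
  double wx = px - x1, wy = py - y1, wz = pz - z1;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  t = std::max(0.0, std::min(1.0, t));
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// Anti-aliased rasterization of tube segments. `segs` has one row per
// centreline segment: (x1, y1, z1, x2, y2, z2, radius), all in µm. Each voxel
// gets the fraction of an nsub^3 subsample grid lying within the tube; the
// value stored is the max over segments (coverage in [0, 1]). Voxel centres
// are at (index µm) = (i - 1) * spacing for 1-based R indices.
// [[Rcpp::export]]
NumericVector cc_raster_tubes(IntegerVector dim, NumericVector spacing,
                              NumericMatrix segs, int nsub) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int ns3 = nsub * nsub * nsub;

  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r = segs(s, 6);
    double r2 = r * r;
    double pad_x = r + sx, pad_y = r + sy, pad_z = r + sz;
    int ix0 = std::max(0, (int)std::floor((std::min(x1, x2) - pad_x) / sx));
    int ix1 = std::min(nx - 1, (int)std::ceil((std::max(x1, x2) + pad_x) / sx));
    int iy0 = std::max(0, (int)std::floor((std::min(y1, y2) - pad_y) / sy));
    int iy1 = std::min(ny - 1, (int)std::ceil((std::max(y1, y2) + pad_y) / sy));
    int iz0 = std::max(0, (int)std::floor((std::min(z1, z2) - pad_z) / sz));
    int iz1 = std::min(nz - 1, (int)std::ceil((std::max(z1, z2) + pad_z) / sz));
    for (int z = iz0; z <= iz1; ++z)
      for (int y = iy0; y <= iy1; ++y)
        for (int x = ix0; x <= ix1; ++x) {
          double cx = x * sx, cy = y * sy, cz = z * sz;
          // cheap reject: centre farther than radius + half voxel diagonal
          double d2 = seg_dist2(cx, cy, cz, x1, y1, z1, x2, y2, z2);
          double hd = 0.5 * std::sqrt(sx * sx + sy * sy + sz * sz);
          double lim = r + hd;
          if (d2 > lim * lim) continue;
          int inside = 0;
          for (int a = 0; a < nsub; ++a)
            for (int b = 0; b < nsub; ++b)
              for (int c = 0; c < nsub; ++c) {
                double ox = cx + ((a + 0.5) / nsub - 0.5) * sx;
                double oy = cy + ((b + 0.5) / nsub - 0.5) * sy;
                double oz = cz + ((c + 0.5) / nsub - 0.5) * sz;
                if (seg_dist2(ox, oy, oz, x1, y1, z1, x2, y2, z2) <= r2)
                  ++inside;
              }
          if (!inside) continue;
          double cov = (double)inside / ns3;
          R_xlen_t idx = x + nx * (y + (R_xlen_t)ny * z);
          if (cov > vol[idx]) vol[idx] = cov;
        }
  }
  return vol;
}
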