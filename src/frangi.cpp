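#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Eigenvalues of a symmetric 3x3 matrix, trigonometric closed form.
static inline void eig3(double a11, double a22, double a33,
                        double a12, double a13, double a23,
                        double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det(B)/2 with B = (A - qI)/p
    double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
    double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
    double detB = c11 * (c22 * c33 - c23 * c23)
                - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13);
    double r = detB / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  // sort by absolute value: |ev[0]| <= |ev[1]| <= |ev[2]|
  std::sort(ev, ev + 3, [](double a, double b) {
    return std::fabs(a) < std::fabs(b);
  });
}

// Frangi vesselness for bright tubular structures from the six unique
// Hessian components. c <= 0 means: use half the maximum Frobenius norm.
// [[Rcpp::export]]
NumericVector cc_frangi(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                        NumericVector hxy, NumericVector hxz, NumericVector hyz,
                        double alpha, double beta, double c) {
  const R_xlen_t n = hxx.size();
  NumericVector out(n);
  double cc = c;
  if (cc <= 0) {
    double smax = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double s2 = hxx[i] * hxx[i] + hyy[i] * hyy[i] + hzz[i] * hzz[i]
                + 2 * (hxy[i] * hxy[i] + hxz[i] * hxz[i] + hyz[i] * hyz[i]);
      if (s2 > smax) smax = s2;
    }
    cc = 0.5 * std::sqrt(smax);
    if (cc == 0) cc = 1.0;
  }
  const double a2 = 2 * alpha * alpha, b2 = 2 * beta * beta, c2 = 2 * cc * cc;
  double ev[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig3(hxx[i], hyy[i], hzz[i], hxy[i], hxz[i], hyz[i], ev);
    double l1 = ev[0], l2 = ev[1], l3 = ev[2];
    if (l2 >= 0 || l3 >= 0) { out[i] = 0.0; continue; }  // bright-on-dark only
    double ra = std::fabs(l2) / std::fabs(l3);
    double rb = std::fabs(l1) / std::sqrt(std::fabs(l2 * l3));
    double s2 = l1 * l1 + l2 * l2 + l3 * l3;
    out[i] = (1.0 - std::exp(-ra * ra / a2)) *
             std::exp(-rb * rb / b2) *
             (1.0 - std::exp(-s2 / c2));
  }
  return out;
}
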