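#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

// Real, fully normalized (orthonormal on the unit sphere) spherical harmonic
// basis evaluated at direction (theta, phi):
//   Y_{l,0}       = Qbar_l^0(cos theta)
//   Y_{l,m>0}     = sqrt(2) * Qbar_l^m(cos theta) * cos(m phi)
//   Y_{l,-m}      = sqrt(2) * Qbar_l^m(cos theta) * sin(m phi)
// with Qbar_l^m = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!) * P_l^m (no
// Condon-Shortley phase). Columns are ordered by idx = l^2 + l + m + 1.
// Normalization implies a constant-radius-r surface has the single nonzero
// coefficient c_{0,0} = r * sqrt(4 pi).

// [[Rcpp::export]]
NumericMatrix cpp_sh_basis(NumericVector theta, NumericVector phi, int lmax) {
  const int n = theta.size();
  if (phi.size() != n) stop("theta and phi must have equal length");
  if (lmax < 0) stop("lmax must be >= 0");
  const int ncoef = (lmax + 1) * (lmax + 1);
  NumericMatrix B(n, ncoef);
  // Qbar recurrences (stable for lmax up to a few hundred; we use <= 16).
  std::vector<double> Q((lmax + 1) * (lmax + 1), 0.0); // Q[l*(lmax+1)+m]
  const double q00 = std::sqrt(1.0 / (4.0 * M_PI));
  for (int i = 0; i < n; ++i) {
    const double x = std::cos(theta[i]);
    const double s = std::sin(theta[i]);
    Q[0] = q00;
    for (int m = 1; m <= lmax; ++m) {
      Q[m * (lmax + 1) + m] =
        s * std::sqrt((2.0 * m + 1.0) / (2.0 * m)) * Q[(m - 1) * (lmax + 1) + (m - 1)];
    }
    for (int m = 0; m < lmax; ++m) {
      Q[(m + 1) * (lmax + 1) + m] = x * std::sqrt(2.0 * m + 3.0) * Q[m * (lmax + 1) + m];
    }
    for (int m = 0; m <= lmax; ++m) {
      for (int l = m + 2; l <= lmax; ++l) {
        const double a = std::sqrt((4.0 * l * l - 1.0) / ((double)l * l - (double)m * m));
        const double b = std::sqrt((((double)(l - 1) * (l - 1)) - (double)m * m) /
                                   (4.0 * (double)(l - 1) * (l - 1) - 1.0));
        Q[l * (lmax + 1) + m] =
          a * (x * Q[(l - 1) * (lmax + 1) + m] - b * Q[(l - 2) * (lmax + 1) + m]);
      }
    }
    const double sq2 = std::sqrt(2.0);
    for (int l = 0; l <= lmax; ++l) {
      const int base = l * l + l; // idx for m = 0 (0-based: base)
      B(i, base) = Q[l * (lmax + 1)];
      for (int m = 1; m <= l; ++m) {
        const double q = Q[l * (lmax + 1) + m];
        B(i, base + m) = sq2 * q * std::cos(m * phi[i]);
        B(i, base - m) = sq2 * q * std::sin(m * phi[i]);
      }
    }
  }
  return B;
}

// 6-connected component labeling of a 3D logical array (flattened,
// column-major, dims = c(nx, ny, nz)). Returns integer labels (0 = background)
// with attribute "n" = number of components.

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (mask.size() != ntot) stop("mask length does not match dims");
  IntegerVector lab(ntot, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++current;
    stack.clear();
    stack.push_back(start);
    lab[start] = current;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz;
        if (mask[w] && lab[w] == 0) {
          lab[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n") = current;
  return lab;
}
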