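// Compiled kernels for speckle tracking and phantom rendering:
//  - Catmull-Rom bicubic sampling with analytic gradient
//  - damped Gauss-Newton affine (Lagrangian) motion estimator
//  - normalized cross-correlation lag surface
//  - scatterer -> RF frame rendering with a separable PSF
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Catmull-Rom (a = -0.5) cubic convolution weights for samples at -1,0,1,2
static inline void cubw(double t, double* w, double* dw) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] =  1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] =  0.5 * t3 - 0.5 * t2;
  if (dw) {
    dw[0] = -1.5 * t2 + 2.0 * t - 0.5;
    dw[1] =  4.5 * t2 - 5.0 * t;
    dw[2] = -4.5 * t2 + 4.0 * t + 0.5;
    dw[3] =  1.5 * t2 - 1.0 * t;
  }
}

// Sample img at fractional 0-based (y = row/axial, x = col/lateral).
// Valid domain needs a one-sample interior margin for the 4x4 stencil.
static inline bool bicubic(const arma::mat& img, double y, double x,
                           double& v, double* gy, double* gx) {
  const int ny = img.n_rows, nx = img.n_cols;
  if (!(y >= 1.0 && y < (double)ny - 2.0 && x >= 1.0 && x < (double)nx - 2.0))
    return false;
  const int iy = (int)std::floor(y), ix = (int)std::floor(x);
  const double ty = y - iy, tx = x - ix;
  double wy[4], dwy[4], wx[4], dwx[4];
  cubw(ty, wy, gy ? dwy : (double*)0);
  cubw(tx, wx, gx ? dwx : (double*)0);
  double s = 0, sy = 0, sx = 0;
  for (int a = 0; a < 4; ++a) {
    double rowv = 0, rowd = 0;
    for (int b = 0; b < 4; ++b) {
      const double p = img(iy - 1 + a, ix - 1 + b);
      rowv += wx[b] * p;
      if (gx) rowd += dwx[b] * p;
    }
    s += wy[a] * rowv;
    if (gy) sy += dwy[a] * rowv;
    if (gx) sx += wy[a] * rowd;
  }
  v = s;
  if (gy) *gy = sy;
  if (gx) *gx = sx;
  return true;
}

// [[Rcpp::export]]
NumericVector bicubic_sample_cpp(const arma::mat& img, NumericVector y,
                                 NumericVector x) {
  const int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v;
    out[i] = bicubic(img, y[i], x[i], v, 0, 0) ? v : NA_REAL;
  }
  return out;
}

// Minimise sum over the window of (p1 - p2(warp))^2 over
// theta = (T1, T2, Dxx, Dxy, Dyx, Dyy).  p2 may be a padded patch; pixel
// (i, j) of p1 corresponds to (i + off_ax, j + off_lat) in p2 coordinates.
// Warp of p1 pixel (i, j), with (dy, dx) offsets from the window centre:
//   y2 = i + off_ax + T2 + Dyx*dx + Dyy*dy
//   x2 = j + off_lat + T1 + Dxx*dx + Dxy*dy
// [[Rcpp::export]]
List lsme_gn_cpp(const arma::mat& p1, const arma::mat& p2, double off_ax,
                 double off_lat, arma::vec init, int max_iter, double tol,
                 double bound) {
  const int n1 = p1.n_rows, m1 = p1.n_cols;
  const double cy = (n1 - 1) / 2.0, cx = (m1 - 1) / 2.0;
  const int npix = n1 * m1;
  const double tmax_ax = p2.n_rows / 2.0, tmax_lat = p2.n_cols / 2.0;

  arma::vec theta = init;  // T1 T2 Dxx Dxy Dyx Dyy
  auto clampv = [&](arma::vec& th) {
    th[0] = std::min(std::max(th[0], -tmax_lat), tmax_lat);
    th[1] = std::min(std::max(th[1], -tmax_ax), tmax_ax);
    for (int k = 2; k < 6; ++k)
      th[k] = std::min(std::max(th[k], -bound), bound);
  };
  clampv(theta);

  // cost + (optionally) normal equations at theta
  arma::mat AtA(6, 6);
  arma::vec Ate(6);
  double ssd_ref = arma::accu(p1 % p1);
  int n_used = 0;
  auto eval = [&](const arma::vec& th, bool with_J, double& cost) -> int {
    cost = 0.0;
    int used = 0;
    if (with_J) { AtA.zeros(); Ate.zeros(); }
    for (int j = 0; j < m1; ++j) {
      const double dx = j - cx;
      for (int i = 0; i < n1; ++i) {
        const double dy = i - cy;
        const double y2 = i + off_ax + th[1] + th[4] * dx + th[5] * dy;
        const double x2 = j + off_lat + th[0] + th[2] * dx + th[3] * dy;
        double v, gy, gx;
        if (!bicubic(p2, y2, x2, v, with_J ? &gy : (double*)0,
                     with_J ? &gx : (double*)0))
          continue;
        const double e = p1(i, j) - v;
        cost += e * e;
        ++used;
        if (with_J) {
          // A = d(model)/d(theta)
          double A[6] = {gx, gy, gx * dx, gx * dy, gy * dx, gy * dy};
          for (int a = 0; a < 6; ++a) {
            Ate[a] += A[a] * e;
            for (int b = a; b < 6; ++b) AtA(a, b) += A[a] * A[b];
          }
        }
      }
    }
    if (with_J)
      for (int a = 0; a < 6; ++a)
        for (int b = 0; b < a; ++b) AtA(a, b) = AtA(b, a);
    return used;
  };

  bool converged = false;
  double cost;
  int it = 0;
  double lambda = 1e-3;
  n_used = eval(theta, true, cost);
  if (n_used < std::max(10, npix / 2)) {
    return List::create(_["par"] = theta, _["residual"] = NA_REAL,
                        _["converged"] = false, _["iters"] = 0,
                        _["n_used"] = n_used);
  }
  for (it = 0; it < max_iter; ++it) {
    bool stepped = false;
    for (int tryk = 0; tryk < 8; ++tryk) {
      arma::mat M = AtA;
      M.diag() += lambda * (AtA.diag() + 1e-12);
      arma::vec delta;
      bool ok = arma::solve(delta, M, Ate, arma::solve_opts::no_approx);
      if (!ok) { lambda *= 10; continue; }
      arma::vec cand = theta + delta;
      clampv(cand);
      double cost2;
      int used2 = eval(cand, false, cost2);
      if (used2 >= std::max(10, npix / 2) && cost2 <= cost) {
        const double dmax = arma::abs(cand - theta).max();
        theta = cand;
        lambda = std::max(lambda / 3.0, 1e-8);
        n_used = eval(theta, true, cost);
        stepped = true;
        if (dmax < tol) converged = true;
        break;
      }
      lambda *= 10;
    }
    if (!stepped) { converged = true; break; }  // no improving step left
    if (converged) break;
  }
  const double resid = ssd_ref > 0 ? cost / ssd_ref : cost;
  return List::create(_["par"] = theta, _["residual"] = resid,
                      _["converged"] = converged, _["iters"] = it + 1,
                      _["n_used"] = n_used);
}

// NCC of a vs b displaced by (dy, dx), over their overlap, for all integer
// lags |dy| <= max_ax, |dx| <= max_lat.  A positive lag means the content of
// b sits 'lag' samples deeper/righter than in a.
// [[Rcpp::export]]
NumericMatrix ncc_lags_cpp(const arma::mat& a, const arma::mat& b, int max_ax,
                           int max_lat) {
  const int ny = a.n_rows, nx = a.n_cols;
  NumericMatrix out(2 * max_ax + 1, 2 * max_lat + 1);
  for (int dy = -max_ax; dy <= max_ax; ++dy) {
    for (int dx = -max_lat; dx <= max_lat; ++dx) {
      const int i0 = std::max(0, -dy), i1 = std::min(ny, (int)b.n_rows - dy);
      const int j0 = std::max(0, -dx), j1 = std::min(nx, (int)b.n_cols - dx);
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      long n = 0;
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) {
          const double va = a(i, j), vb = b(i + dy, j + dx);
          sa += va; sb += vb; saa += va * va; sbb += vb * vb; sab += va * vb;
          ++n;
        }
      double v = NA_REAL;
      if (n >= 4) {
        const double cab = sab - sa * sb / n;
        const double caa = saa - sa * sa / n;
        const double cbb = sbb - sb * sb / n;
        if (caa > 1e-12 && cbb > 1e-12) v = cab / std::sqrt(caa * cbb);
      }
      out(dy + max_ax, dx + max_lat) = v;
    }
  }
  return out;
}

// Sum of separable point-spread functions: axially a Gaussian-windowed cosine
// (k_ax radians per sample), laterally a Gaussian; truncated at rad_z/rad_x.
// Scatterer positions are fractional 0-based (sample, line) coordinates.
// [[Rcpp::export]]
arma::mat render_rf_cpp(const arma::vec& zs, const arma::vec& xs,
                        const arma::vec& amps, int nz, int nx, double k_ax,
                        double sig_z, double sig_x, double rad_z,
                        double rad_x) {
  arma::mat out(nz, nx, arma::fill::zeros);
  const double i2z = 1.0 / (2.0 * sig_z * sig_z);
  const double i2x = 1.0 / (2.0 * sig_x * sig_x);
  for (arma::uword s = 0; s < zs.n_elem; ++s) {
    const double z = zs[s], x = xs[s], a = amps[s];
    const int i0 = std::max(0, (int)std::ceil(z - rad_z));
    const int i1 = std::min(nz - 1, (int)std::floor(z + rad_z));
    const int j0 = std::max(0, (int)std::ceil(x - rad_x));
    const int j1 = std::min(nx - 1, (int)std::floor(x + rad_x));
    if (i0 > i1 || j0 > j1) continue;
    for (int j = j0; j <= j1; ++j) {
      const double dxl = j - x;
      const double wl = std::exp(-dxl * dxl * i2x);
      for (int i = i0; i <= i1; ++i) {
        const double dz = i - z;
        out(i, j) += a * wl * std::exp(-dz * dz * i2z) * std::cos(k_ax * dz);
      }
    }
  }
  return out;
}
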