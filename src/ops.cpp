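#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// All volumes are R arrays in column-major order: linear index
// i + nx*(j + ny*k) for voxel (i,j,k), 0-based here.

static inline int reflect_index(int p, int n) {
  // half-sample symmetric reflection (d c b a | a b c d), matches Neumann
  if (n == 1) return 0;
  int period = 2 * n;
  p %= period;
  if (p < 0) p += period;
  if (p >= n) p = period - 1 - p;
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_conv_axis(const NumericVector& arr, const IntegerVector& dim,
                            const NumericVector& kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size();
  const int half = kl / 2; // kernel assumed odd length, centered
  NumericVector out(arr.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int na = n[axis], sa = stride[axis];
  // iterate over lines along `axis`
  const int nb = (axis == 0) ? ny : nx;
  const int nc = (axis == 2) ? ny : nz;
  const int sb = (axis == 0) ? stride[1] : stride[0];
  const int sc = (axis == 2) ? stride[1] : stride[2];
  std::vector<double> line(na);
  for (int c = 0; c < nc; ++c) {
    for (int b = 0; b < nb; ++b) {
      const int base = b * sb + c * sc;
      for (int a = 0; a < na; ++a) line[a] = arr[base + a * sa];
      for (int a = 0; a < na; ++a) {
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
          int p = reflect_index(a + t - half, na);
          acc += kernel[t] * line[p];
        }
        out[base + a * sa] = acc;
      }
    }
  }
  return out;
}

static inline double tri_sample(const NumericVector& vals, const int* dim,
                                double cx, double cy, double cz,
                                bool nearest, double fill, bool* inside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  *inside = true;
  if (nearest) {
    int i = (int)std::lround(cx), j = (int)std::lround(cy), k = (int)std::lround(cz);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) { *inside = false; return fill; }
    return vals[i + nx * (j + ny * (size_t)k)];
  }
  if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1 || cz < 0 || cz > nz - 1) {
    *inside = false; return fill;
  }
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double tx = cx - i0, ty = cy - j0, tz = cz - k0;
  if (nx == 1) tx = 0; if (ny == 1) ty = 0; if (nz == 1) tz = 0;
  int i1 = (nx == 1) ? i0 : i0 + 1, j1 = (ny == 1) ? j0 : j0 + 1, k1 = (nz == 1) ? k0 : k0 + 1;
  const size_t nxy = (size_t)nx * ny;
  double v000 = vals[i0 + nx * j0 + nxy * k0], v100 = vals[i1 + nx * j0 + nxy * k0];
  double v010 = vals[i0 + nx * j1 + nxy * k0], v110 = vals[i1 + nx * j1 + nxy * k0];
  double v001 = vals[i0 + nx * j0 + nxy * k1], v101 = vals[i1 + nx * j0 + nxy * k1];
  double v011 = vals[i0 + nx * j1 + nxy * k1], v111 = vals[i1 + nx * j1 + nxy * k1];
  double c00 = v000 * (1 - tx) + v100 * tx, c10 = v010 * (1 - tx) + v110 * tx;
  double c01 = v001 * (1 - tx) + v101 * tx, c11 = v011 * (1 - tx) + v111 * tx;
  double c0 = c00 * (1 - ty) + c10 * ty, c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export]]
NumericVector cpp_affine_resample(const NumericVector& vals, const IntegerVector& dimIn,
                                  const NumericVector& spacingIn, const NumericVector& originIn,
                                  const NumericMatrix& lin, const NumericVector& trans,
                                  const IntegerVector& dimOut, const NumericVector& spacingOut,
                                  const NumericVector& originOut, bool nearest, double fill) {
  const int nx = dimOut[0], ny = dimOut[1], nz = dimOut[2];
  int din[3] = {dimIn[0], dimIn[1], dimIn[2]};
  NumericVector out((size_t)nx * ny * nz);
  double L[9];
  for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c) L[r * 3 + c] = lin(r, c);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double wz = originOut[2] + k * spacingOut[2];
    for (int j = 0; j < ny; ++j) {
      double wy = originOut[1] + j * spacingOut[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double wx = originOut[0] + i * spacingOut[0];
        double mx = L[0] * wx + L[1] * wy + L[2] * wz + trans[0];
        double my = L[3] * wx + L[4] * wy + L[5] * wz + trans[1];
        double mz = L[6] * wx + L[7] * wy + L[8] * wz + trans[2];
        double cx = (mx - originIn[0]) / spacingIn[0];
        double cy = (my - originIn[1]) / spacingIn[1];
        double cz = (mz - originIn[2]) / spacingIn[2];
        bool inside;
        out[idx] = tri_sample(vals, din, cx, cy, cz, nearest, fill, &inside);
      }
    }
  }
  return out;
}

// 1-D squared distance transform of sampled function f at positions x_i = i*s
// (lower-envelope-of-parabolas algorithm); entries of f may be +Inf
static void dt1d(const std::vector<double>& f, int n, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    while (true) {
      double xv = v[k] * s;
      double ss = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (ss <= z[k]) {
        k--;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; break; }
      } else {
        k++; v[k] = q; z[k] = ss; z[k + 1] = INF; break;
      }
    }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[kk + 1] < xq) kk++;
    double xv = v[kk] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[kk]];
  }
}

// Euclidean distance (mm) to the nearest nonzero voxel center; Inf if mask empty
// [[Rcpp::export]]
NumericVector cpp_edt(const NumericVector& mask, const IntegerVector& dim,
                      const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = (mask[i] != 0) ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    size_t base = (size_t)nx * (j + (size_t)ny * k);
    for (int i = 0; i < nx; ++i) f[i] = g[base + i];
    dt1d(f, nx, spacing[0], d, v, z);
    for (int i = 0; i < nx; ++i) g[base + i] = d[i];
  }
  // y axis
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) f[j] = g[i + (size_t)nx * (j + (size_t)ny * k)];
    dt1d(f, ny, spacing[1], d, v, z);
    for (int j = 0; j < ny; ++j) g[i + (size_t)nx * (j + (size_t)ny * k)] = d[j];
  }
  // z axis
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) f[k] = g[i + (size_t)nx * (j + (size_t)ny * k)];
    dt1d(f, nz, spacing[2], d, v, z);
    for (int k = 0; k < nz; ++k) g[i + (size_t)nx * (j + (size_t)ny * k)] = d[k];
  }
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = std::isinf(g[i]) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// value + spatial gradient (d/dmm) of trilinear interpolant at world points
// [[Rcpp::export]]
NumericMatrix cpp_sample_grad(const NumericVector& vals, const IntegerVector& dim,
                              const NumericVector& spacing, const NumericVector& origin,
                              const NumericMatrix& pts, double fill) {
  const int K = pts.nrow();
  int din[3] = {dim[0], dim[1], dim[2]};
  NumericMatrix out(K, 5); // value, gx, gy, gz, inside
  const double h = 0.5;    // half-voxel central difference in voxel units
  for (int s = 0; s < K; ++s) {
    double c[3];
    for (int a = 0; a < 3; ++a) c[a] = (pts(s, a) - origin[a]) / spacing[a];
    bool inside;
    double val = tri_sample(vals, din, c[0], c[1], c[2], false, fill, &inside);
    out(s, 0) = val;
    out(s, 4) = inside ? 1.0 : 0.0;
    for (int a = 0; a < 3; ++a) {
      double cp[3] = {c[0], c[1], c[2]}, cm[3] = {c[0], c[1], c[2]};
      cp[a] += h; cm[a] -= h;
      bool in1, in2;
      double vp = tri_sample(vals, din, cp[0], cp[1], cp[2], false, val, &in1);
      double vm = tri_sample(vals, din, cm[0], cm[1], cm[2], false, val, &in2);
      out(s, 1 + a) = (vp - vm) / (2 * h * spacing[a]);
    }
  }
  return out;
}

// interpolate a volume at world points (trilinear or nearest)
// [[Rcpp::export]]
NumericVector cpp_sample_points(const NumericVector& vals, const IntegerVector& dim,
                                const NumericVector& spacing, const NumericVector& origin,
                                const NumericMatrix& pts, bool nearest, double fill) {
  const int K = pts.nrow();
  int din[3] = {dim[0], dim[1], dim[2]};
  NumericVector out(K);
  for (int s = 0; s < K; ++s) {
    double cx = (pts(s, 0) - origin[0]) / spacing[0];
    double cy = (pts(s, 1) - origin[1]) / spacing[1];
    double cz = (pts(s, 2) - origin[2]) / spacing[2];
    bool inside;
    out[s] = tri_sample(vals, din, cx, cy, cz, nearest, fill, &inside);
  }
  return out;
}

static inline void bspline_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// cubic B-spline displacement (mm) at world points; coef is ncp x 3 (mm),
// lattice indexed so that point u in [0, ncp-3] uses cps floor(u)..floor(u)+3
// [[Rcpp::export]]
NumericMatrix cpp_ffd_disp(const NumericMatrix& coef, const IntegerVector& ldim,
                           const NumericVector& lorigin, const NumericVector& lspacing,
                           const NumericMatrix& pts) {
  const int K = pts.nrow();
  const int cx = ldim[0], cy = ldim[1], cz = ldim[2];
  NumericMatrix out(K, 3);
  for (int s = 0; s < K; ++s) {
    double u[3]; int b[3]; double W[3][4];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(s, a) - lorigin[a]) / lspacing[a];
      int nc = (a == 0) ? cx : (a == 1) ? cy : cz;
      // outside the covered domain the spline sum has no supporting control
      // points: the displacement is identically zero there
      if (nc < 4 || u[a] < 0.0 || u[a] > nc - 3.0) { ok = false; break; }
      int fl = (int)std::floor(u[a]);
      double t = u[a] - fl;
      if (fl > nc - 4) { fl = nc - 4; t = u[a] - fl; }
      b[a] = fl; bspline_w(t, W[a]);
    }
    double dx = 0, dy = 0, dz = 0;
    if (ok) {
      for (int kk = 0; kk < 4; ++kk) for (int jj = 0; jj < 4; ++jj) for (int ii = 0; ii < 4; ++ii) {
        double w = W[0][ii] * W[1][jj] * W[2][kk];
        if (w == 0) continue;
        int cp = (b[0] + ii) + cx * ((b[1] + jj) + cy * (b[2] + kk));
        dx += w * coef(cp, 0); dy += w * coef(cp, 1); dz += w * coef(cp, 2);
      }
    }
    out(s, 0) = dx; out(s, 1) = dy; out(s, 2) = dz;
  }
  return out;
}

// scatter per-sample vectors into control-point gradient with B-spline weights
// [[Rcpp::export]]
NumericMatrix cpp_ffd_accum(const IntegerVector& ldim, const NumericVector& lorigin,
                            const NumericVector& lspacing, const NumericMatrix& pts,
                            const NumericMatrix& vec) {
  const int K = pts.nrow();
  const int cx = ldim[0], cy = ldim[1], cz = ldim[2];
  NumericMatrix grad(cx * cy * cz, 3);
  for (int s = 0; s < K; ++s) {
    double u[3]; int b[3]; double W[3][4];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(s, a) - lorigin[a]) / lspacing[a];
      int nc = (a == 0) ? cx : (a == 1) ? cy : cz;
      if (nc < 4 || u[a] < 0.0 || u[a] > nc - 3.0) { ok = false; break; }
      int fl = (int)std::floor(u[a]);
      double t = u[a] - fl;
      if (fl > nc - 4) { fl = nc - 4; t = u[a] - fl; }
      b[a] = fl; bspline_w(t, W[a]);
    }
    if (!ok) continue;
    for (int kk = 0; kk < 4; ++kk) for (int jj = 0; jj < 4; ++jj) for (int ii = 0; ii < 4; ++ii) {
      double w = W[0][ii] * W[1][jj] * W[2][kk];
      if (w == 0) continue;
      int cp = (b[0] + ii) + cx * ((b[1] + jj) + cy * (b[2] + kk));
      grad(cp, 0) += w * vec(s, 0);
      grad(cp, 1) += w * vec(s, 1);
      grad(cp, 2) += w * vec(s, 2);
    }
  }
  return grad;
}

// Parzen-window joint histogram MI (nats) and dMI/dm_k.
// f, m already on their own intensity scales; fixed gets a linear (hat)
// window, moving a cubic B-spline window (Mattes-style).
// [[Rcpp::export]]
List cpp_mi_grad(const NumericVector& f, const NumericVector& m, int nbins,
                 double fmin, double fmax, double mmin, double mmax,
                 bool want_grad) {
  const int K = f.size();
  const double fscale = (nbins - 1) / std::max(fmax - fmin, 1e-12);
  const double mscale = (nbins - 3) / std::max(mmax - mmin, 1e-12);
  std::vector<double> H((size_t)nbins * nbins, 0.0);
  std::vector<int> fb0(K); std::vector<double> fw0(K);
  std::vector<int> mb0(K); std::vector<double> mt(K);
  double wm[4], dwm[4];
  for (int s = 0; s < K; ++s) {
    double alpha = (f[s] - fmin) * fscale;
    if (alpha < 0) alpha = 0; if (alpha > nbins - 1) alpha = nbins - 1;
    int a0 = (int)std::floor(alpha); if (a0 == nbins - 1) a0--;
    if (a0 < 0) a0 = 0;
    double ta = alpha - a0;
    fb0[s] = a0; fw0[s] = 1.0 - ta;
    double beta = (m[s] - mmin) * mscale + 1.0;
    if (beta < 1) beta = 1; if (beta > nbins - 2) beta = nbins - 2;
    int b0 = (int)std::floor(beta);
    if (b0 > nbins - 3) b0 = nbins - 3;
    double tb = beta - b0;
    mb0[s] = b0; mt[s] = tb;
    bspline_w(tb, wm);
    for (int q = 0; q < 4; ++q) {
      int bb = b0 - 1 + q;
      H[(size_t)fb0[s] + (size_t)nbins * bb] += fw0[s] * wm[q];
      H[(size_t)(fb0[s] + 1) + (size_t)nbins * bb] += (1.0 - fw0[s]) * wm[q];
    }
  }
  double invK = 1.0 / K;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int b = 0; b < nbins; ++b) for (int a = 0; a < nbins; ++a) {
    double p = H[(size_t)a + (size_t)nbins * b] * invK;
    H[(size_t)a + (size_t)nbins * b] = p;
    pf[a] += p; pm[b] += p;
  }
  double mi = 0.0;
  for (int b = 0; b < nbins; ++b) for (int a = 0; a < nbins; ++a) {
    double p = H[(size_t)a + (size_t)nbins * b];
    if (p > 1e-14 && pf[a] > 1e-14 && pm[b] > 1e-14)
      mi += p * std::log(p / (pf[a] * pm[b]));
  }
  NumericVector dmi;
  if (want_grad) {
    dmi = NumericVector(K);
    for (int s = 0; s < K; ++s) {
      double tb = mt[s];
      double t2 = tb * tb;
      // derivatives of the four cubic B-spline weights wrt tb
      dwm[0] = (-3 + 6 * tb - 3 * t2) / 6.0;
      dwm[1] = (-12 * tb + 9 * t2) / 6.0;
      dwm[2] = (3 + 6 * tb - 9 * t2) / 6.0;
      dwm[3] = 3 * t2 / 6.0;
      double acc = 0.0;
      for (int part = 0; part < 2; ++part) {
        int a = fb0[s] + part;
        double wa = part == 0 ? fw0[s] : 1.0 - fw0[s];
        if (wa == 0) continue;
        for (int q = 0; q < 4; ++q) {
          int bb = mb0[s] - 1 + q;
          double p = H[(size_t)a + (size_t)nbins * bb];
          if (p > 1e-14 && pm[bb] > 1e-14)
            acc += wa * dwm[q] * std::log(p / pm[bb]);
        }
      }
      dmi[s] = acc * invK * mscale; // chain through bin coordinate
    }
  }
  return List::create(_["mi"] = mi, _["dmi_dm"] = dmi);
}
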