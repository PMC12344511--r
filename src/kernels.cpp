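#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Continuous 0-based voxel coordinates throughout. A point p samples the
// trilinear interpolant of `vol`; outside [0, n-1]^3 the declared background
// is returned unless `clamp` pins coordinates to the grid boundary.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
NumericVector interp3_cpp(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                          double background, bool nearest, bool clamp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (clamp) {
      x = clampd(x, 0.0, nx - 1.0);
      y = clampd(y, 0.0, ny - 1.0);
      z = clampd(z, 0.0, nz - 1.0);
    } else if (x < 0 || y < 0 || z < 0 || x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[p] = background;
      continue;
    }
    if (nearest) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      out[p] = v[(R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k)];
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (i0 < 0) { i0 = 0; fx = 0.0; } if (i0 >= nx - 1) { i0 = nx - 1; fx = 0.0; }
    if (j0 < 0) { j0 = 0; fy = 0.0; } if (j0 >= ny - 1) { j0 = ny - 1; fy = 0.0; }
    if (k0 < 0) { k0 = 0; fz = 0.0; } if (k0 >= nz - 1) { k0 = nz - 1; fz = 0.0; }
    // zero-fraction axes collapse onto the base voxel so that integer
    // coordinates reproduce grid values bit-exactly
    R_xlen_t sx = (fx > 0.0) ? 1 : 0, sy = (fy > 0.0) ? nx : 0,
             sz = (fz > 0.0) ? (R_xlen_t)nx * ny : 0;
    R_xlen_t base = (R_xlen_t)i0 + nx * ((R_xlen_t)j0 + (R_xlen_t)ny * k0);
    double c000 = v[base],           c100 = v[base + sx];
    double c010 = v[base + sy],      c110 = v[base + sx + sy];
    double c001 = v[base + sz],      c101 = v[base + sx + sz];
    double c011 = v[base + sy + sz], c111 = v[base + sx + sy + sz];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    out[p] = c0 + fz * (c1 - c0);
  }
  return out;
}

// Value and exact partial derivatives of the trilinear interpolant with
// respect to the continuous voxel coordinates. Outside the grid (no clamp)
// value = background and derivatives are zero; with clamp, the derivative
// along a clamped coordinate is zero.
// [[Rcpp::export]]
NumericMatrix interp3_grad_cpp(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                               double background, bool clamp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 4);
  const double *v = vol.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool cx = false, cy = false, cz = false;
    if (clamp) {
      if (x < 0 || x > nx - 1.0) { x = clampd(x, 0.0, nx - 1.0); cx = true; }
      if (y < 0 || y > ny - 1.0) { y = clampd(y, 0.0, ny - 1.0); cy = true; }
      if (z < 0 || z > nz - 1.0) { z = clampd(z, 0.0, nz - 1.0); cz = true; }
    } else if (x < 0 || y < 0 || z < 0 || x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out(p, 0) = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    R_xlen_t base = (R_xlen_t)i0 + nx * ((R_xlen_t)j0 + (R_xlen_t)ny * k0);
    R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double c000 = v[base],           c100 = v[base + sx];
    double c010 = v[base + sy],      c110 = v[base + sx + sy];
    double c001 = v[base + sz],      c101 = v[base + sx + sz];
    double c011 = v[base + sy + sz], c111 = v[base + sx + sy + sz];
    double gx = 1 - fx, gy = 1 - fy, gz = 1 - fz;
    out(p, 0) = gz * (gy * (gx * c000 + fx * c100) + fy * (gx * c010 + fx * c110)) +
                fz * (gy * (gx * c001 + fx * c101) + fy * (gx * c011 + fx * c111));
    out(p, 1) = cx ? 0.0 :
      gz * (gy * (c100 - c000) + fy * (c110 - c010)) +
      fz * (gy * (c101 - c001) + fy * (c111 - c011));
    out(p, 2) = cy ? 0.0 :
      gz * (gx * (c010 - c000) + fx * (c110 - c100)) +
      fz * (gx * (c011 - c001) + fx * (c111 - c101));
    out(p, 3) = cz ? 0.0 :
      gy * (gx * (c001 - c000) + fx * (c101 - c100)) +
      fy * (gx * (c011 - c010) + fx * (c111 - c110));
  }
  return out;
}

// Catmull-Rom (interpolating cubic) sampling; sharper reconstruction than
// trilinear for resampling steps whose output is interpolated again.
// Border cells clamp the stencil; outside the grid -> background.
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

// [[Rcpp::export]]
NumericVector interp3_cubic_cpp(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[p] = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    double wx[4], wy[4], wz[4];
    cr_weights(x - i0, wx);
    cr_weights(y - j0, wy);
    cr_weights(z - k0, wz);
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
      int kk = k0 - 1 + c;
      if (kk < 0) kk = 0; if (kk > nz - 1) kk = nz - 1;
      double accy = 0.0;
      for (int b = 0; b < 4; ++b) {
        int jj = j0 - 1 + b;
        if (jj < 0) jj = 0; if (jj > ny - 1) jj = ny - 1;
        R_xlen_t base = sy * jj + sz * kk;
        double accx = 0.0;
        for (int a = 0; a < 4; ++a) {
          int ii = i0 - 1 + a;
          if (ii < 0) ii = 0; if (ii > nx - 1) ii = nx - 1;
          accx += wx[a] * v[base + ii];
        }
        accy += wy[b] * accx;
      }
      acc += wz[c] * accy;
    }
    out[p] = acc;
  }
  return out;
}

// Value and exact analytic gradient of the Catmull-Rom interpolant: a C^1
// image model whose derivatives vary smoothly across voxel boundaries,
// unlike the piecewise-linear model. Outside the grid: background, zero
// gradient.
static inline void cr_dweights(double t, double w[4]) {
  double t2 = t * t;
  w[0] = -1.5 * t2 + 2.0 * t - 0.5;
  w[1] = 4.5 * t2 - 5.0 * t;
  w[2] = -4.5 * t2 + 4.0 * t + 0.5;
  w[3] = 1.5 * t2 - t;
}

// [[Rcpp::export]]
NumericMatrix interp3_cubic_grad_cpp(NumericVector vol, IntegerVector dim,
                                     NumericMatrix pts, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 4);
  const double *v = vol.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out(p, 0) = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    double wx[4], wy[4], wz[4], dx[4], dy[4], dz[4];
    cr_weights(x - i0, wx); cr_dweights(x - i0, dx);
    cr_weights(y - j0, wy); cr_dweights(y - j0, dy);
    cr_weights(z - k0, wz); cr_dweights(z - k0, dz);
    double val = 0, gx = 0, gy = 0, gz = 0;
    for (int c = 0; c < 4; ++c) {
      int kk = k0 - 1 + c;
      if (kk < 0) kk = 0; if (kk > nz - 1) kk = nz - 1;
      for (int b = 0; b < 4; ++b) {
        int jj = j0 - 1 + b;
        if (jj < 0) jj = 0; if (jj > ny - 1) jj = ny - 1;
        R_xlen_t base = sy * jj + sz * kk;
        double sx_v = 0, sx_d = 0;
        for (int a = 0; a < 4; ++a) {
          int ii = i0 - 1 + a;
          if (ii < 0) ii = 0; if (ii > nx - 1) ii = nx - 1;
          double cv = v[base + ii];
          sx_v += wx[a] * cv;
          sx_d += dx[a] * cv;
        }
        val += wz[c] * wy[b] * sx_v;
        gx += wz[c] * wy[b] * sx_d;
        gy += wz[c] * dy[b] * sx_v;
        gz += dz[c] * wy[b] * sx_v;
      }
    }
    out(p, 0) = val; out(p, 1) = gx; out(p, 2) = gy; out(p, 3) = gz;
  }
  return out;
}

// Felzenszwalb & Huttenlocher lower envelope of parabolas, one scan line.
// f: squared distances at sample positions i*h; result overwrites f.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &vtx, std::vector<double> &zb,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  vtx[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[vtx[0]] == INF) { k = 0; vtx[0] = q; zb[0] = -INF; zb[1] = INF; continue; }
    double s;
    while (true) {
      int vp = vtx[k];
      s = ((f[q] + h2 * q * q) - (f[vp] + h2 * vp * vp)) / (2.0 * h2 * (q - vp));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  if (f[vtx[0]] == INF) { return; } // no seeds on this line
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[kk + 1] < q) ++kk;
    double dq = h * (q - vtx[kk]);
    d[q] = dq * dq + f[vtx[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean distance transform (mm) from a seed set on an anisotropic
// grid; non-seed voxels start at +Inf.
// [[Rcpp::export]]
NumericVector edt3_cpp(LogicalVector seed, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(ntot);
  double *o = out.begin();
  for (R_xlen_t i = 0; i < ntot; ++i) o[i] = seed[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> vtx(nmax);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) f[i] = o[base + sx * i];
      dt1d(f, d, vtx, zb, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) o[base + sx * i] = f[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = sx * i + sz * k;
      for (int j = 0; j < ny; ++j) f[j] = o[base + sy * j];
      dt1d(f, d, vtx, zb, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) o[base + sy * j] = f[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = sx * i + sy * j;
      for (int k = 0; k < nz; ++k) f[k] = o[base + sz * k];
      dt1d(f, d, vtx, zb, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) o[base + sz * k] = f[k];
    }
  for (R_xlen_t i = 0; i < ntot; ++i) o[i] = std::sqrt(o[i]);
  return out;
}

// Spacing-aware 6-neighbour Laplacian with Neumann (replicated-edge)
// boundaries; the workhorse of the curvature term and its Gauss-Newton
// operator, so it avoids the array copies of an R shift implementation.
// [[Rcpp::export]]
NumericVector laplacian3_cpp(NumericVector a, IntegerVector dim,
                             NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double wx = 1.0 / (spacing[0] * spacing[0]);
  const double wy = 1.0 / (spacing[1] * spacing[1]);
  const double wz = 1.0 / (spacing[2] * spacing[2]);
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *v = a.begin();
  double *o = out.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = base + i;
        double c = v[p];
        double acc = 0.0;
        acc += wx * ((i > 0 ? v[p - 1] : c) + (i < nx - 1 ? v[p + 1] : c) - 2.0 * c);
        acc += wy * ((j > 0 ? v[p - sy] : c) + (j < ny - 1 ? v[p + sy] : c) - 2.0 * c);
        acc += wz * ((k > 0 ? v[p - sz] : c) + (k < nz - 1 ? v[p + sz] : c) - 2.0 * c);
        o[p] = acc;
      }
    }
  }
  return out;
}

// 6-connected component labelling; background voxels get 0.
// [[Rcpp::export]]
IntegerVector label6_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot);
  int cur = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / (sz));
      R_xlen_t nb[6];
      int nn = 0;
      if (i > 0) nb[nn++] = p - sx;
      if (i < nx - 1) nb[nn++] = p + sx;
      if (j > 0) nb[nn++] = p - sy;
      if (j < ny - 1) nb[nn++] = p + sy;
      if (k > 0) nb[nn++] = p - sz;
      if (k < nz - 1) nb[nn++] = p + sz;
      for (int t = 0; t < nn; ++t) {
        R_xlen_t u = nb[t];
        if (mask[u] && lab[u] == 0) { lab[u] = cur; q.push(u); }
      }
    }
  }
  return lab;
}
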