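#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Cubic B-spline basis on the unit interval; nodes floor(t)-1 .. floor(t)+2.
static inline void bspline_weights(double f, double *w) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (3.0 * f3 - 6.0 * f2 + 4.0) / 6.0;
  w[2] = (-3.0 * f3 + 3.0 * f2 + 3.0 * f + 1.0) / 6.0;
  w[3] = f3 / 6.0;
}

static inline void bspline_dweights(double f, double *d) {
  const double f2 = f * f;
  d[0] = -(1.0 - f) * (1.0 - f) / 2.0;
  d[1] = (3.0 * f2 - 4.0 * f) / 2.0;
  d[2] = (-3.0 * f2 + 2.0 * f + 1.0) / 2.0;
  d[3] = f2 / 2.0;
}

// Displacement of a cubic B-spline FFD at physical points.
// coef: (nx*ny*nz) x 3, node (i,j,k) at row i + nx*(j + ny*k).
// Nodes outside the grid contribute zero displacement.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericMatrix pts, NumericVector origin,
                               NumericVector spacing, IntegerVector dims,
                               NumericMatrix coef) {
  const int n = pts.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    double t0 = (pts(p, 0) - origin[0]) / spacing[0];
    double t1 = (pts(p, 1) - origin[1]) / spacing[1];
    double t2 = (pts(p, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(t0), j0 = (int)std::floor(t1),
        k0 = (int)std::floor(t2);
    bspline_weights(t0 - i0, wx);
    bspline_weights(t1 - j0, wy);
    bspline_weights(t2 - k0, wz);
    double u0 = 0.0, u1 = 0.0, u2 = 0.0;
    for (int c = 0; c < 4; ++c) {
      int kk = k0 - 1 + c;
      if (kk < 0 || kk >= nz) continue;
      for (int b = 0; b < 4; ++b) {
        int jj = j0 - 1 + b;
        if (jj < 0 || jj >= ny) continue;
        const double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          int ii = i0 - 1 + a;
          if (ii < 0 || ii >= nx) continue;
          const double w = wx[a] * wyz;
          const int idx = ii + nx * (jj + ny * kk);
          u0 += w * coef(idx, 0);
          u1 += w * coef(idx, 1);
          u2 += w * coef(idx, 2);
        }
      }
    }
    out(p, 0) = u0; out(p, 1) = u1; out(p, 2) = u2;
  }
  return out;
}

// Spatial Jacobian of the displacement field; row p holds the 3x3 matrix
// J[i][j] = du_i/dx_j stored column-major (J as filled by matrix(x, 3, 3)).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_jac(NumericMatrix pts, NumericVector origin,
                              NumericVector spacing, IntegerVector dims,
                              NumericMatrix coef) {
  const int n = pts.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(n, 9);
  double wx[4], wy[4], wz[4], dx[4], dy[4], dz[4];
  for (int p = 0; p < n; ++p) {
    double t0 = (pts(p, 0) - origin[0]) / spacing[0];
    double t1 = (pts(p, 1) - origin[1]) / spacing[1];
    double t2 = (pts(p, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(t0), j0 = (int)std::floor(t1),
        k0 = (int)std::floor(t2);
    bspline_weights(t0 - i0, wx); bspline_dweights(t0 - i0, dx);
    bspline_weights(t1 - j0, wy); bspline_dweights(t1 - j0, dy);
    bspline_weights(t2 - k0, wz); bspline_dweights(t2 - k0, dz);
    double J[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int c = 0; c < 4; ++c) {
      int kk = k0 - 1 + c;
      if (kk < 0 || kk >= nz) continue;
      for (int b = 0; b < 4; ++b) {
        int jj = j0 - 1 + b;
        if (jj < 0 || jj >= ny) continue;
        for (int a = 0; a < 4; ++a) {
          int ii = i0 - 1 + a;
          if (ii < 0 || ii >= nx) continue;
          const int idx = ii + nx * (jj + ny * kk);
          const double g0 = dx[a] * wy[b] * wz[c] / spacing[0];
          const double g1 = wx[a] * dy[b] * wz[c] / spacing[1];
          const double g2 = wx[a] * wy[b] * dz[c] / spacing[2];
          for (int i = 0; i < 3; ++i) {
            const double ci = coef(idx, i);
            J[0 + i] += ci * g0;   // du_i/dx0 -> column 0
            J[3 + i] += ci * g1;   // du_i/dx1 -> column 1
            J[6 + i] += ci * g2;   // du_i/dx2 -> column 2
          }
        }
      }
    }
    for (int q = 0; q < 9; ++q) out(p, q) = J[q];
  }
  return out;
}

// Scatter-accumulate point values onto B-spline coefficient nodes with the
// interpolation weights: grad[node, d] += w(p, node) * vals(p, d).
// Adjoint of cpp_bspline_disp; used for analytic cost gradients.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_scatter(NumericMatrix pts, NumericMatrix vals,
                                  NumericVector origin, NumericVector spacing,
                                  IntegerVector dims) {
  const int n = pts.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nx * ny * nz, 3);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    double t0 = (pts(p, 0) - origin[0]) / spacing[0];
    double t1 = (pts(p, 1) - origin[1]) / spacing[1];
    double t2 = (pts(p, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(t0), j0 = (int)std::floor(t1),
        k0 = (int)std::floor(t2);
    bspline_weights(t0 - i0, wx);
    bspline_weights(t1 - j0, wy);
    bspline_weights(t2 - k0, wz);
    const double v0 = vals(p, 0), v1 = vals(p, 1), v2 = vals(p, 2);
    for (int c = 0; c < 4; ++c) {
      int kk = k0 - 1 + c;
      if (kk < 0 || kk >= nz) continue;
      for (int b = 0; b < 4; ++b) {
        int jj = j0 - 1 + b;
        if (jj < 0 || jj >= ny) continue;
        const double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          int ii = i0 - 1 + a;
          if (ii < 0 || ii >= nx) continue;
          const double w = wx[a] * wyz;
          const int idx = ii + nx * (jj + ny * kk);
          out(idx, 0) += w * v0;
          out(idx, 1) += w * v1;
          out(idx, 2) += w * v2;
        }
      }
    }
  }
  return out;
}

// Trilinear sampling of a volume at physical points (identity direction).
// Outside the volume -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample_linear(NumericVector vol, IntegerVector dim,
                                NumericVector origin, NumericVector spacing,
                                NumericMatrix pts, double fill) {
  const int n = pts.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double t0 = (pts(p, 0) - origin[0]) / spacing[0];
    double t1 = (pts(p, 1) - origin[1]) / spacing[1];
    double t2 = (pts(p, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(t0), j0 = (int)std::floor(t1),
        k0 = (int)std::floor(t2);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx - 1 || j0 >= ny - 1 ||
        k0 >= nz - 1) {
      // allow exact top boundary
      if (t0 >= 0 && t1 >= 0 && t2 >= 0 && t0 <= nx - 1 && t1 <= ny - 1 &&
          t2 <= nz - 1) {
        if (i0 == nx - 1) i0--;
        if (j0 == ny - 1) j0--;
        if (k0 == nz - 1) k0--;
      } else {
        out[p] = fill;
        continue;
      }
    }
    const double fx = t0 - i0, fy = t1 - j0, fz = t2 - k0;
    const int s = i0 + nx * (j0 + ny * k0);
    const int sx = 1, sy = nx, sz = nx * ny;
    const double c000 = vol[s], c100 = vol[s + sx];
    const double c010 = vol[s + sy], c110 = vol[s + sx + sy];
    const double c001 = vol[s + sz], c101 = vol[s + sx + sz];
    const double c011 = vol[s + sy + sz], c111 = vol[s + sx + sy + sz];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (masks / binary volumes).
// [[Rcpp::export]]
NumericVector cpp_sample_nn(NumericVector vol, IntegerVector dim,
                            NumericVector origin, NumericVector spacing,
                            NumericMatrix pts, double fill) {
  const int n = pts.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    int i = (int)std::lround((pts(p, 0) - origin[0]) / spacing[0]);
    int j = (int)std::lround((pts(p, 1) - origin[1]) / spacing[1]);
    int k = (int)std::lround((pts(p, 2) - origin[2]) / spacing[2]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
      out[p] = fill;
    } else {
      out[p] = vol[i + nx * (j + ny * k)];
    }
  }
  return out;
}

static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  const int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double ksum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + radius];
  }
  for (auto &x : k) x /= ksum;
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int len = n[axis], st = stride[axis];
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int j2 = 0; j2 < n[a2]; ++j2) {
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      const int base = j1 * stride[a1] + j2 * stride[a2];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int q = -radius; q <= radius; ++q) {
          int ii = i + q;               // reflect boundary
          if (ii < 0) ii = -ii - 1;
          if (ii >= len) ii = 2 * len - ii - 1;
          acc += k[q + radius] * v[base + ii * st];
        }
        tmp[i] = acc;
      }
      for (int i = 0; i < len; ++i) v[base + i * st] = tmp[i];
    }
  }
}

// Separable Gaussian blur, sigma per axis in voxel units, reflect boundary.
// [[Rcpp::export]]
NumericVector cpp_blur_sep(NumericVector vol, IntegerVector dim,
                           NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> tmp(std::max(nx, std::max(ny, nz)));
  for (int ax = 0; ax < 3; ++ax) blur_axis(v, tmp, nx, ny, nz, ax, sigma_vox[ax]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// 1-D squared distance transform (lower envelope of parabolas),
// sample locations i*h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n, std::vector<int> &v,
                 std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    while (true) {
      if (f[v[k]] == INF) { // uninitialised parabola, replace
        v[k] = q;
        z[k + 1] = INF;
        break;
      }
      double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
                 (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    if (f[v[kk]] == INF) { d[q] = INF; continue; }
    const double dq = h * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
}

// Euclidean distance (mm) from each foreground voxel to the nearest
// background voxel (exact, separable; anisotropic spacing supported).
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  const int maxn = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxn), d(maxn), z(maxn + 1);
  std::vector<int> v(maxn);
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = n[ax], st = stride[ax];
    const int a1 = (ax + 1) % 3, a2 = (ax + 2) % 3;
    for (int j2 = 0; j2 < n[a2]; ++j2) {
      for (int j1 = 0; j1 < n[a1]; ++j1) {
        const size_t base = (size_t)j1 * stride[a1] + (size_t)j2 * stride[a2];
        for (int i = 0; i < len; ++i) f[i] = g[base + (size_t)i * st];
        dt1d(f, d, spacing[ax], len, v, z);
        for (int i = 0; i < len; ++i) g[base + (size_t)i * st] = d[i];
      }
    }
  }
  NumericVector out(g.size());
  for (size_t i = 0; i < g.size(); ++i)
    out[i] = std::isinf(g[i]) ? NA_REAL : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// Trilinear lookup into a binary volume (voxel-center convention); returns
// -1 outside the volume.
static inline double sample_bin(const IntegerVector &vol, int nx, int ny,
                                int nz, double tx, double ty, double tz) {
  int i0 = (int)std::floor(tx), j0 = (int)std::floor(ty),
      k0 = (int)std::floor(tz);
  if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx - 1 || j0 >= ny - 1 ||
      k0 >= nz - 1)
    return -1.0;
  const double fx = tx - i0, fy = ty - j0, fz = tz - k0;
  const int s = i0 + nx * (j0 + ny * k0);
  const int sy = nx, sz = nx * ny;
  const double c00 = vol[s] * (1 - fx) + vol[s + 1] * fx;
  const double c10 = vol[s + sy] * (1 - fx) + vol[s + 1 + sy] * fx;
  const double c01 = vol[s + sz] * (1 - fx) + vol[s + 1 + sz] * fx;
  const double c11 = vol[s + sy + sz] * (1 - fx) + vol[s + 1 + sy + sz] * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// MIL line casting. For each test direction: a parallel grid of lines with
// in-plane spacing `line_spacing` (mm) is marched through the volume with
// sampling step `step` (mm). The binary phase is probed by trilinear
// interpolation against the 0.5 iso-level, which suppresses the staircase
// bias a nearest-neighbour marcher shows along oblique directions. Returns
// per direction the in-bone length (mm) and the number of marrow->bone
// transitions.
// [[Rcpp::export]]
NumericMatrix cpp_mil(IntegerVector vol, IntegerVector dim,
                      NumericVector spacing, NumericMatrix dirs,
                      double line_spacing, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  const double cx = ex / 2.0, cy = ey / 2.0, cz = ez / 2.0;
  const double radius = 0.5 * std::sqrt(ex * ex + ey * ey + ez * ez);
  const int K = dirs.nrow();
  NumericMatrix out(K, 2);
  for (int kdir = 0; kdir < K; ++kdir) {
    double w0 = dirs(kdir, 0), w1 = dirs(kdir, 1), w2 = dirs(kdir, 2);
    // orthonormal in-plane frame
    double a0, a1, a2;
    if (std::fabs(w0) < 0.9) { a0 = 1; a1 = 0; a2 = 0; }
    else { a0 = 0; a1 = 1; a2 = 0; }
    double e10 = a1 * w2 - a2 * w1, e11 = a2 * w0 - a0 * w2,
           e12 = a0 * w1 - a1 * w0;
    double n1 = std::sqrt(e10 * e10 + e11 * e11 + e12 * e12);
    e10 /= n1; e11 /= n1; e12 /= n1;
    double e20 = w1 * e12 - w2 * e11, e21 = w2 * e10 - w0 * e12,
           e22 = w0 * e11 - w1 * e10;
    long bone_samples = 0;
    long transitions = 0;
    const int noff = (int)std::floor(radius / line_spacing);
    const int nstep = (int)std::floor(radius / step);
    for (int ia = -noff; ia <= noff; ++ia) {
      for (int ib = -noff; ib <= noff; ++ib) {
        const double ox = cx + ia * line_spacing * e10 + ib * line_spacing * e20;
        const double oy = cy + ia * line_spacing * e11 + ib * line_spacing * e21;
        const double oz = cz + ia * line_spacing * e12 + ib * line_spacing * e22;
        int prev = -1; // -1: outside / not yet in volume
        for (int is = -nstep; is <= nstep; ++is) {
          const double px = ox + is * step * w0;
          const double py = oy + is * step * w1;
          const double pz = oz + is * step * w2;
          const double g = sample_bin(vol, nx, ny, nz,
                                      px / spacing[0] - 0.5,
                                      py / spacing[1] - 0.5,
                                      pz / spacing[2] - 0.5);
          if (g < 0) {
            prev = -1;
            continue;
          }
          const int val = g >= 0.5 ? 1 : 0;
          if (val) ++bone_samples;
          if (prev == 0 && val == 1) ++transitions;
          prev = val;
        }
      }
    }
    out(kdir, 0) = bone_samples * step;
    out(kdir, 1) = (double)transitions;
  }
  return out;
}
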