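// Low-level 3D image kernels: trilinear sampling, separable Gaussian blur,
// exact Euclidean distance transform, connected components, local thickness,
// affine resampling and the Gauss-Newton assembly for grid-based DVC.
// Arrays are R column-major: index (i,j,k) -> i + nx*(j + ny*k), voxel
// centers at 0-based integer coordinates.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline size_t IDX(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// Trilinear sample with edge clamping.
static double tri_sample_clamp(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
  if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
  if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
  double fx = nx > 1 ? x - i0 : 0.0;
  double fy = ny > 1 ? y - j0 : 0.0;
  double fz = nz > 1 ? z - k0 : 0.0;
  int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
  double c000 = v[IDX(i0,j0,k0,nx,ny)], c100 = v[IDX(i1,j0,k0,nx,ny)];
  double c010 = v[IDX(i0,j1,k0,nx,ny)], c110 = v[IDX(i1,j1,k0,nx,ny)];
  double c001 = v[IDX(i0,j0,k1,nx,ny)], c101 = v[IDX(i1,j0,k1,nx,ny)];
  double c011 = v[IDX(i0,j1,k1,nx,ny)], c111 = v[IDX(i1,j1,k1,nx,ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Trilinear sample; coordinates outside [0, n-1] return `fill`.
static double tri_sample_fill(const double* v, int nx, int ny, int nz,
                              double x, double y, double z, double fill) {
  const double eps = 1e-9;
  if (x < -eps || x > nx - 1 + eps || y < -eps || y > ny - 1 + eps ||
      z < -eps || z > nz - 1 + eps)
    return fill;
  return tri_sample_clamp(v, nx, ny, nz, x, y, z);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims,
                                double sigma, int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0 || radius < 1) return clone(vol);
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (double& w : kern) w /= s;
  NumericVector out(n);
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(n);
  // mirror boundary, one axis at a time
  for (int axis = 0; axis < 3; ++axis) {
    int nAx = axis == 0 ? nx : (axis == 1 ? ny : nz);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0;
          for (int t = -radius; t <= radius; ++t) {
            int p = axis == 0 ? i + t : (axis == 1 ? j + t : k + t);
            if (p < 0) p = -p;
            if (p > nAx - 1) p = 2 * (nAx - 1) - p;
            if (p < 0) p = 0;  // degenerate tiny axis
            int ii = axis == 0 ? p : i, jj = axis == 1 ? p : j, kk = axis == 2 ? p : k;
            acc += kern[t + radius] * buf[IDX(ii, jj, kk, nx, ny)];
          }
          tmp[IDX(i, j, k, nx, ny)] = acc;
        }
    buf.swap(tmp);
  }
  std::copy(buf.begin(), buf.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double>& f, int n, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in voxels) from each foreground voxel to the nearest
// background voxel center; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> D(n);
  for (size_t i = 0; i < n; ++i) D[i] = fg[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[IDX(i, j, k, nx, ny)];
      dt1d(f, nx, d, v, zb);
      for (int i = 0; i < nx; ++i) D[IDX(i, j, k, nx, ny)] = d[i];
    }
  // y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[IDX(i, j, k, nx, ny)];
      dt1d(f, ny, d, v, zb);
      for (int j = 0; j < ny; ++j) D[IDX(i, j, k, nx, ny)] = d[j];
    }
  // z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[IDX(i, j, k, nx, ny)];
      dt1d(f, nz, d, v, zb);
      for (int k = 0; k < nz; ++k) D[IDX(i, j, k, nx, ny)] = d[k];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}

// Largest 26-connected foreground component.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector fg, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  std::vector<size_t> stack;
  int cur = 0;
  size_t bestSize = 0;
  int bestLab = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!fg[s] || label[s]) continue;
    ++cur;
    size_t sz = 0;
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      ++sz;
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((size_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            size_t q = IDX(ii, jj, kk, nx, ny);
            if (fg[q] && !label[q]) { label[q] = cur; stack.push_back(q); }
          }
    }
    if (sz > bestSize) { bestSize = sz; bestLab = cur; }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (label[i] == bestLab) && bestLab > 0;
  out.attr("dim") = dims;
  return out;
}

// Fill cavities: background 6-connected to the volume border stays background,
// fully enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector fg, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i && j && k && i < nx - 1 && j < ny - 1 && k < nz - 1) continue;
        size_t p = IDX(i, j, k, nx, ny);
        if (!fg[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    size_t p = stack.back();
    stack.pop_back();
    int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((size_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      size_t q = IDX(ii, jj, kk, nx, ny);
      if (!fg[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = fg[i] || !outside[i];
  out.attr("dim") = dims;
  return out;
}

// Hildebrand-Rueegsegger local thickness map (voxel units): every foreground
// voxel q seeds a sphere of diameter 2*D(q)-1; each covered voxel keeps the
// largest diameter of any sphere containing it.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector D = cpp_edt(fg, dims);
  NumericVector th(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = IDX(i, j, k, nx, ny);
        double r = D[p];
        if (r <= 0) continue;
        // skip spheres entirely contained in a neighbour's sphere
        bool dominated = false;
        for (int dk = -1; dk <= 1 && !dominated; ++dk)
          for (int dj = -1; dj <= 1 && !dominated; ++dj)
            for (int di = -1; di <= 1 && !dominated; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              double dd = std::sqrt((double)(di*di + dj*dj + dk*dk));
              if (D[IDX(ii,jj,kk,nx,ny)] >= r + dd) dominated = true;
            }
        if (dominated) continue;
        double val = 2.0 * r;
        double pr = r;  // sphere covers voxels whose centers it contains
        int R = (int)std::floor(pr);
        double pr2 = pr * pr + 1e-9;
        for (int dk = -R; dk <= R; ++dk)
          for (int dj = -R; dj <= R; ++dj)
            for (int di = -R; di <= R; ++di) {
              if ((double)(di * di + dj * dj + dk * dk) > pr2) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              size_t q = IDX(ii, jj, kk, nx, ny);
              if (th[q] < val) th[q] = val;
            }
      }
  th.attr("dim") = dims;
  return th;
}

// Resample under the affine inverse map X = M x + t (voxel coordinates);
// source points outside the volume get `fill`.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dims,
                                  NumericMatrix M, NumericVector t, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double* v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double X = M(0,0)*i + M(0,1)*j + M(0,2)*k + t[0];
        double Y = M(1,0)*i + M(1,1)*j + M(1,2)*k + t[1];
        double Z = M(2,0)*i + M(2,1)*j + M(2,2)*k + t[2];
        out[IDX(i,j,k,nx,ny)] = tri_sample_fill(v, nx, ny, nz, X, Y, Z, fill);
      }
  out.attr("dim") = dims;
  return out;
}

// 2x2x2 block mean; output dims are floor(n/2).
// [[Rcpp::export]]
NumericVector cpp_block_halve(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector out((size_t)mx * my * mz);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              acc += vol[IDX(2*i+di, 2*j+dj, 2*k+dk, nx, ny)];
        out[(size_t)i + (size_t)mx * ((size_t)j + (size_t)my * k)] = acc / 8.0;
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}

// Trilinear sample with the analytic gradient of the interpolant (exact
// derivative of the sampled objective, so Gauss-Newton stationary points
// coincide with minima of the discrete SSD). Clamped at edges (zero
// gradient along a clamped axis).
static double tri_sample_grad(const double* v, int nx, int ny, int nz,
                              double x, double y, double z, double* g) {
  bool cx = false, cy = false, cz = false;
  if (x < 0) { x = 0; cx = true; } if (x > nx - 1) { x = nx - 1; cx = true; }
  if (y < 0) { y = 0; cy = true; } if (y > ny - 1) { y = ny - 1; cy = true; }
  if (z < 0) { z = 0; cz = true; } if (z > nz - 1) { z = nz - 1; cz = true; }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
  if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
  if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
  double fx = nx > 1 ? x - i0 : 0.0;
  double fy = ny > 1 ? y - j0 : 0.0;
  double fz = nz > 1 ? z - k0 : 0.0;
  int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
  double c000 = v[IDX(i0,j0,k0,nx,ny)], c100 = v[IDX(i1,j0,k0,nx,ny)];
  double c010 = v[IDX(i0,j1,k0,nx,ny)], c110 = v[IDX(i1,j1,k0,nx,ny)];
  double c001 = v[IDX(i0,j0,k1,nx,ny)], c101 = v[IDX(i1,j0,k1,nx,ny)];
  double c011 = v[IDX(i0,j1,k1,nx,ny)], c111 = v[IDX(i1,j1,k1,nx,ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  g[0] = cx ? 0.0 :
    ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
    ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz;
  g[1] = cy ? 0.0 : (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
  g[2] = cz ? 0.0 : c1 - c0;
  return c0 * (1 - fz) + c1 * fz;
}

// Catmull-Rom cubic-convolution kernel weights and derivatives for
// fractional offset t in [0,1): taps at -1, 0, 1, 2.
static inline void cr_weights(double t, double* w, double* dw) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
  dw[0] = -1.5 * t2 + 2.0 * t - 0.5;
  dw[1] = 4.5 * t2 - 5.0 * t;
  dw[2] = -4.5 * t2 + 4.0 * t + 0.5;
  dw[3] = 1.5 * t2 - t;
}

// Cubic-convolution sample with analytic gradient; coordinates clamped to
// the volume, gradient zeroed along clamped axes. Much lower sub-voxel
// interpolation bias than trilinear sampling.
static double cubic_sample_grad(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double* g) {
  bool cx = false, cy = false, cz = false;
  if (x < 0) { x = 0; cx = true; } if (x > nx - 1) { x = nx - 1; cx = true; }
  if (y < 0) { y = 0; cy = true; } if (y > ny - 1) { y = ny - 1; cy = true; }
  if (z < 0) { z = 0; cz = true; } if (z > nz - 1) { z = nz - 1; cz = true; }
  int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
  int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
  int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double wx[4], dwx[4], wy[4], dwy[4], wz[4], dwz[4];
  cr_weights(fx, wx, dwx);
  cr_weights(fy, wy, dwy);
  cr_weights(fz, wz, dwz);
  int ix[4], jy[4], kz[4];
  for (int t = 0; t < 4; ++t) {
    ix[t] = std::min(std::max(i0 - 1 + t, 0), nx - 1);
    jy[t] = std::min(std::max(j0 - 1 + t, 0), ny - 1);
    kz[t] = std::min(std::max(k0 - 1 + t, 0), nz - 1);
  }
  double val = 0, gx = 0, gy = 0, gz = 0;
  for (int c = 0; c < 4; ++c) {
    double pzw = wz[c], pzd = dwz[c];
    for (int b = 0; b < 4; ++b) {
      double row = 0;
      double rowd = 0;
      const double* base = v + (size_t)nx * ((size_t)jy[b] + (size_t)ny * kz[c]);
      for (int a = 0; a < 4; ++a) {
        double cv = base[ix[a]];
        row += wx[a] * cv;
        rowd += dwx[a] * cv;
      }
      val += row * wy[b] * pzw;
      gx += rowd * wy[b] * pzw;
      gy += row * dwy[b] * pzw;
      gz += row * wy[b] * pzd;
    }
  }
  g[0] = cx ? 0.0 : gx;
  g[1] = cy ? 0.0 : gy;
  g[2] = cz ? 0.0 : gz;
  return val;
}

// Gauss-Newton assembly for grid-based registration with SSD metric.
// Nodes sit at voxel coordinates {0, ns, 2ns, ...} (ncounts per axis);
// u is the current nodal displacement (voxel units, N x 3, x-fastest node
// ordering). Returns GtG (3N x 3N, unknowns ordered [ux | uy | uz]), Gtr,
// the SSD over contributing voxels, the voxel count, and per-node shape
// weight sums (coverage bookkeeping).
// [[Rcpp::export]]
List cpp_dvc_assemble(NumericVector fixedv, NumericVector movingv,
                      LogicalVector mask, IntegerVector dims,
                      int ns, IntegerVector ncounts, NumericMatrix u,
                      int order = 3) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nnx = ncounts[0], nny = ncounts[1], nnz = ncounts[2];
  int N = nnx * nny * nnz;
  int M3 = 3 * N;
  NumericMatrix GtG(M3, M3);
  NumericVector Gtr(M3), wsum(N);
  double ssd = 0;
  size_t nvox = 0;
  const double* mv = movingv.begin();
  int nodeIdx[8];
  double w[8], rowg[24];
  int cols[24];
  int maxx = (nnx - 1) * ns, maxy = (nny - 1) * ns, maxz = (nnz - 1) * ns;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = IDX(i,j,k,nx,ny);
        if (!mask[p]) continue;
        if (i > maxx || j > maxy || k > maxz) continue;  // outside the grid
        int ci = std::min(i / ns, nnx - 2), cj = std::min(j / ns, nny - 2),
            ck = std::min(k / ns, nnz - 2);
        double fx = (i - ci * ns) / (double)ns;
        double fy = (j - cj * ns) / (double)ns;
        double fz = (k - ck * ns) / (double)ns;
        int c = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              nodeIdx[c] = (ci + di) + nnx * ((cj + dj) + nny * (ck + dk));
              w[c] = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
              ++c;
            }
        double ux = 0, uy = 0, uz = 0;
        for (c = 0; c < 8; ++c) {
          ux += w[c] * u(nodeIdx[c], 0);
          uy += w[c] * u(nodeIdx[c], 1);
          uz += w[c] * u(nodeIdx[c], 2);
          wsum[nodeIdx[c]] += w[c];
        }
        double X = i + ux, Y = j + uy, Z = k + uz;
        double gv[3];
        double m = (order >= 3)
          ? cubic_sample_grad(mv, nx, ny, nz, X, Y, Z, gv)
          : tri_sample_grad(mv, nx, ny, nz, X, Y, Z, gv);
        double g0 = gv[0], g1 = gv[1], g2 = gv[2];
        double r = fixedv[p] - m;
        ssd += r * r;
        ++nvox;
        for (c = 0; c < 8; ++c) {
          rowg[c]      = g0 * w[c]; cols[c]      = nodeIdx[c];
          rowg[8 + c]  = g1 * w[c]; cols[8 + c]  = N + nodeIdx[c];
          rowg[16 + c] = g2 * w[c]; cols[16 + c] = 2 * N + nodeIdx[c];
        }
        for (int a = 0; a < 24; ++a) {
          double ga = rowg[a];
          if (ga == 0) continue;
          Gtr[cols[a]] += ga * r;
          for (int b = a; b < 24; ++b) {
            double gb = rowg[b];
            if (gb == 0) continue;
            GtG(cols[a], cols[b]) += ga * gb;
          }
        }
      }
  // symmetrize
  for (int a = 0; a < M3; ++a)
    for (int b = a + 1; b < M3; ++b)
      GtG(b, a) = GtG(a, b);
  return List::create(_["GtG"] = GtG, _["Gtr"] = Gtr, _["ssd"] = ssd,
                      _["nvox"] = (double)nvox, _["wsum"] = wsum);
}
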