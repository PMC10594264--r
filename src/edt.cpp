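#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// sample spacing w. Only finite parabolas enter the envelope; an all-INF
// line stays INF. f is overwritten with the transformed values.
static void dt1d(std::vector<double>& f, int n, double w, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // displaced the only parabola
      v[k] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite sources on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
  } else {
    int j = 0;
    for (int q = 0; q < n; ++q) {
      while (z[j + 1] < q) ++j;
      double dq = (double)(q - v[j]) * w;
      d[q] = dq * dq + f[v[j]];
    }
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact anisotropic squared EDT of a 3D binary mask (separable passes).
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      f.assign(D.begin() + base, D.begin() + base + nx);
      f.resize(nx);
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) D[base + i] = f[i];
    }
  // pass along y
  f.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  f.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * nx * ny];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * nx * ny] = f[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) D[i] = std::sqrt(D[i]);
  return D;
}

// 3D connected-component labeling, connectivity in {6, 18, 26}.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // build neighbor offset list
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int ci = cur % nx;
      int cj = (cur / nx) % ny;
      int ck = cur / ((R_xlen_t)nx * ny);
      for (size_t t = 0; t < dxs.size(); ++t) {
        int i = ci + dxs[t], j = cj + dys[t], k = ck + dzs[t];
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return lab;
}

// 2D median filter with square window of radius r; the window is clamped at
// image borders (median of available neighbors, as ImageJ's Despeckle does).
// [[Rcpp::export]]
NumericMatrix median2d_cpp(NumericMatrix x, int r) {
  const int nx = x.nrow(), ny = x.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> win;
  win.reserve((2 * r + 1) * (2 * r + 1));
  for (int j = 0; j < ny; ++j) {
    int j0 = std::max(0, j - r), j1 = std::min(ny - 1, j + r);
    for (int i = 0; i < nx; ++i) {
      int i0 = std::max(0, i - r), i1 = std::min(nx - 1, i + r);
      win.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          win.push_back(x(ii, jj));
      size_t m = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + m, win.end());
      double med = win[m];
      if (win.size() % 2 == 0) {
        std::nth_element(win.begin(), win.begin() + m - 1, win.begin() + m);
        med = 0.5 * (med + win[m - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Separable Gaussian blur of a 2D image, replicate boundary, kernel
// truncated at 3 sigma and renormalized.
// [[Rcpp::export]]
NumericMatrix gauss2d_cpp(NumericMatrix x, double sigma) {
  const int nx = x.nrow(), ny = x.ncol();
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + r];
  }
  for (double& v : k) v /= ks;
  NumericMatrix tmp(nx, ny), out(nx, ny);
  for (int j = 0; j < ny; ++j)     // along x
    for (int i = 0; i < nx; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(std::max(i + t, 0), nx - 1);
        acc += k[t + r] * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < ny; ++j)     // along y
    for (int i = 0; i < nx; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(std::max(j + t, 0), ny - 1);
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// Additively stamp solid spheres (voxel-center indicator) into a 3D array,
// in place. centers are um coordinates (rows), radii um, spacing um/voxel.
// [[Rcpp::export]]
void stamp_spheres_cpp(NumericVector arr, IntegerVector dims,
                       NumericMatrix centers, NumericVector radii,
                       double amplitude, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  for (int q = 0; q < centers.nrow(); ++q) {
    double cx = centers(q, 0), cy = centers(q, 1), cz = centers(q, 2);
    double r = radii[q], r2 = r * r;
    int i0 = std::max(0, (int)std::floor((cx - r) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + r) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((cy - r) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + r) / spacing[1]));
    int k0 = std::max(0, (int)std::floor((cz - r) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + r) / spacing[2]));
    for (int k = k0; k <= k1; ++k) {
      double dz = k * spacing[2] - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = j * spacing[1] - cy;
        for (int i = i0; i <= i1; ++i) {
          double dx = i * spacing[0] - cx;
          if (dx * dx + dy * dy + dz * dz <= r2)
            arr[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] += amplitude;
        }
      }
    }
  }
}
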