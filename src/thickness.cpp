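#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared distance transform (lower envelope).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (voxel units) from every voxel to the
// nearest background (0) voxel. Voxels outside the volume are treated as
// structure (open boundary): structures touching the edge continue past it.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double INF = 1e20;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // column-major layout: index = i + n1*j + n1*n2*k
  // pass along dim 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // pass along dim 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // pass along dim 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)n1 * n2 * k];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)n1 * n2 * k] = d[k];
    }
  return out;
}

// Hildebrand-Rueegsegger local thickness by maximal-sphere painting.
// Input: binary structure mask and its squared EDT (voxel units).
// For a structure voxel c the inscribed-sphere radius is
// r(c) = sqrt(edt_sq(c)) - 0.5 (half-voxel correction: the EDT measures to
// the nearest background voxel CENTER, the phase boundary lies half a voxel
// closer). Every voxel x with |x - c| <= r(c) receives at least 2 r(c).
// Output: thickness in voxel units (diameter), 0 outside the structure.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector mask, NumericVector edt_sq,
                                  IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = mask.size();
  NumericVector th(n, 0.0);
  std::vector<R_xlen_t> centers;
  centers.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) centers.push_back(i);
  if (centers.empty()) return th;
  // no background anywhere: thickness is unbounded inside the volume
  bool has_bg = false;
  for (R_xlen_t i = 0; i < n && !has_bg; ++i)
    if (!mask[i]) has_bg = true;
  if (!has_bg) {
    double diam = 2.0 * std::sqrt((double)n1 * n1 + (double)n2 * n2 +
                                  (double)n3 * n3);
    for (R_xlen_t i = 0; i < n; ++i) th[i] = diam;
    return th;
  }
  // paint large spheres first so most later writes are no-ops
  std::sort(centers.begin(), centers.end(),
            [&](R_xlen_t a, R_xlen_t b) { return edt_sq[a] > edt_sq[b]; });
  const double eps = 1e-9;
  for (R_xlen_t ci : centers) {
    double r = std::sqrt(edt_sq[ci]) - 0.5;
    if (r < 0) r = 0;
    double t = 2.0 * r;
    if (th[ci] >= t && r < 0.5 + eps) continue;  // covers only itself
    int i0 = (int)(ci % n1);
    int j0 = (int)((ci / n1) % n2);
    int k0 = (int)(ci / ((R_xlen_t)n1 * n2));
    int ri = (int)std::floor(r + eps);
    double r2 = r * r + eps;
    for (int dk = -ri; dk <= ri; ++dk) {
      int k = k0 + dk;
      if (k < 0 || k >= n3) continue;
      double zk = (double)dk * dk;
      for (int dj = -ri; dj <= ri; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= n2) continue;
        double zj = zk + (double)dj * dj;
        if (zj > r2) continue;
        R_xlen_t base = (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
        int di_max = (int)std::floor(std::sqrt(r2 - zj) + eps);
        int lo = std::max(-di_max, -i0);
        int hi = std::min(di_max, n1 - 1 - i0);
        for (int di = lo; di <= hi; ++di) {
          R_xlen_t idx = base + i0 + di;
          if (th[idx] < t) th[idx] = t;
        }
      }
    }
  }
  return th;
}
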