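#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid, by the
// separable lower-envelope (parabola) algorithm on squared distances.
// Physical sample spacing w per axis: parabola k contributes
// ((q - k) * w)^2 + f[k].  Passes run along z, then y, then x, and each
// candidate is accumulated as s*s + f so the arithmetic matches a
// left-to-right brute-force sum term for term.

static void dt1d(std::vector<double>& f, double w, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb) {
  const int n = (int)f.size();
  const double w2 = w * w;
  int k = -1; // index of last parabola in the envelope; -1 = none yet
  for (int q = 0; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    if (k < 0) {
      k = 0; v[0] = q; zb[0] = -INFINITY; zb[1] = INFINITY;
      continue;
    }
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] - f[p]) / w2 + (double)q * q - (double)p * p) / (2.0 * (q - p));
      if (s <= zb[k]) --k; else break; // zb[0] = -Inf guarantees k >= 0 here
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INFINITY; f = d; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < q) ++j;
    const double s = (double)(q - v[j]) * w;
    d[q] = s * s + f[v[j]];
  }
  f = d;
}

// feature: logical; returns Euclidean distance (micrometres) of every voxel
// to the nearest feature voxel centre. All-false feature -> all Inf.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector feature, IntegerVector dim, NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double wz = voxel[0], wy = voxel[1], wx = voxel[2];
  const R_xlen_t n = feature.size();
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INFINITY;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      f.assign(nz, 0.0);
      for (int z = 0; z < nz; ++z) f[z] = g[z + (size_t)nz * (y + (size_t)ny * x)];
      d.assign(nz, 0.0);
      dt1d(f, wz, d, v, zb);
      for (int z = 0; z < nz; ++z) g[z + (size_t)nz * (y + (size_t)ny * x)] = f[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = g[z + (size_t)nz * (y + (size_t)ny * x)];
      d.assign(ny, 0.0);
      dt1d(f, wy, d, v, zb);
      for (int y = 0; y < ny; ++y) g[z + (size_t)nz * (y + (size_t)ny * x)] = f[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = g[z + (size_t)nz * (y + (size_t)ny * x)];
      d.assign(nx, 0.0);
      dt1d(f, wx, d, v, zb);
      for (int x = 0; x < nx; ++x) g[z + (size_t)nz * (y + (size_t)ny * x)] = f[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Exhaustive O(N_bg * N_feature) reference: min centre-to-centre distance of
// every non-feature voxel to the feature set, accumulated z, y, x.
// [[Rcpp::export(name = ".brute_force_dist_cpp")]]
NumericVector brute_force_dist_cpp(LogicalVector feature, IntegerVector dim,
                                   NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double wz = voxel[0], wy = voxel[1], wx = voxel[2];
  std::vector<int> fz, fy, fx;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (feature[z + (size_t)nz * (y + (size_t)ny * x)]) {
          fz.push_back(z); fy.push_back(y); fx.push_back(x);
        }
  const size_t m = fz.size();
  NumericVector out(feature.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (feature[i]) { out[i] = 0.0; continue; }
        double best = INFINITY;
        for (size_t k = 0; k < m; ++k) {
          const double sz = (double)(z - fz[k]) * wz;
          const double sy = (double)(y - fy[k]) * wy;
          const double sx = (double)(x - fx[k]) * wx;
          double dsq = sz * sz;
          dsq = sy * sy + dsq;
          dsq = sx * sx + dsq;
          if (dsq < best) best = dsq;
        }
        out[i] = std::sqrt(best);
      }
  return out;
}
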