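#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multiscale Hessian (Frangi) tubularity for bright tubes on dark background.
// Physical units throughout: per-axis Gaussian sigma = scale / voxel_dim,
// Hessian by central differences over physical coordinates, gamma = 2 scale
// normalisation (multiply by scale^2).

namespace {

inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// separable Gaussian along one axis; axis: 0=z,1=y,2=x
void gauss_axis(std::vector<double>& vol, int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0.05) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& v : k) v /= s;
  const int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::vector<double> line(n);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < n; ++z) line[z] = vol[z + (size_t)nz * (y + (size_t)ny * x)];
        for (int z = 0; z < n; ++z) {
          double a = 0;
          for (int i = -r; i <= r; ++i) a += k[i + r] * line[reflect(z + i, n)];
          vol[z + (size_t)nz * (y + (size_t)ny * x)] = a;
        }
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < n; ++y) line[y] = vol[z + (size_t)nz * (y + (size_t)ny * x)];
        for (int y = 0; y < n; ++y) {
          double a = 0;
          for (int i = -r; i <= r; ++i) a += k[i + r] * line[reflect(y + i, n)];
          vol[z + (size_t)nz * (y + (size_t)ny * x)] = a;
        }
      }
  } else {
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < n; ++x) line[x] = vol[z + (size_t)nz * (y + (size_t)ny * x)];
        for (int x = 0; x < n; ++x) {
          double a = 0;
          for (int i = -r; i <= r; ++i) a += k[i + r] * line[reflect(x + i, n)];
          vol[z + (size_t)nz * (y + (size_t)ny * x)] = a;
        }
      }
  }
}

// eigenvalues of a symmetric 3x3, ascending (analytic, Smith's method)
void eig3(double a11, double a12, double a13, double a22, double a23, double a33,
          double ev[3]) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    const double q = (a11 + a22 + a33) / 3.0;
    const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                      (a33 - q) * (a33 - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    const double b11 = (a11 - q) / p, b12 = a12 / p, b13 = a13 / p;
    const double b22 = (a22 - q) / p, b23 = a23 / p, b33 = (a33 - q) / p;
    double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    const double phi = std::acos(r) / 3.0;
    ev[2] = q + 2.0 * p * std::cos(phi);
    ev[0] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[2] - ev[0];
  }
  // sort ascending by value
  if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
  if (ev[1] > ev[2]) std::swap(ev[1], ev[2]);
  if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
}

} // namespace

// Separable Gaussian smoothing with per-axis sigma in voxels.
// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> sm(vol.begin(), vol.end());
  gauss_axis(sm, nz, ny, nx, 0, sigma_vox[0]);
  gauss_axis(sm, nz, ny, nx, 1, sigma_vox[1]);
  gauss_axis(sm, nz, ny, nx, 2, sigma_vox[2]);
  return NumericVector(sm.begin(), sm.end());
}

// [[Rcpp::export(name = ".frangi_cpp")]]
NumericVector frangi_cpp(NumericVector vol, IntegerVector dim, NumericVector voxel,
                         NumericVector scales, double alpha, double beta, double cpar) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = voxel[0], dy = voxel[1], dx = voxel[2];
  const R_xlen_t n = vol.size();
  NumericVector out(n, 0.0);
  std::vector<double> sm(n), l1(n), l2(n), l3(n);

  for (double s : scales) {
    for (R_xlen_t i = 0; i < n; ++i) sm[i] = vol[i];
    gauss_axis(sm, nz, ny, nx, 0, s / dz);
    gauss_axis(sm, nz, ny, nx, 1, s / dy);
    gauss_axis(sm, nz, ny, nx, 2, s / dx);

    const double s2 = s * s;
    double smax = 0.0;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          auto at = [&](int zz, int yy, int xx) {
            return sm[reflect(zz, nz) + (size_t)nz * (reflect(yy, ny) + (size_t)ny * reflect(xx, nx))];
          };
          const double c = at(z, y, x);
          const double hzz = (at(z + 1, y, x) - 2 * c + at(z - 1, y, x)) / (dz * dz);
          const double hyy = (at(z, y + 1, x) - 2 * c + at(z, y - 1, x)) / (dy * dy);
          const double hxx = (at(z, y, x + 1) - 2 * c + at(z, y, x - 1)) / (dx * dx);
          const double hzy = (at(z + 1, y + 1, x) - at(z + 1, y - 1, x) -
                              at(z - 1, y + 1, x) + at(z - 1, y - 1, x)) / (4 * dz * dy);
          const double hzx = (at(z + 1, y, x + 1) - at(z + 1, y, x - 1) -
                              at(z - 1, y, x + 1) + at(z - 1, y, x - 1)) / (4 * dz * dx);
          const double hyx = (at(z, y + 1, x + 1) - at(z, y + 1, x - 1) -
                              at(z, y - 1, x + 1) + at(z, y - 1, x - 1)) / (4 * dy * dx);
          double ev[3];
          eig3(s2 * hzz, s2 * hzy, s2 * hzx, s2 * hyy, s2 * hyx, s2 * hxx, ev);
          // order by |lambda|
          double a1 = ev[0], a2 = ev[1], a3 = ev[2];
          if (std::abs(a1) > std::abs(a2)) std::swap(a1, a2);
          if (std::abs(a2) > std::abs(a3)) std::swap(a2, a3);
          if (std::abs(a1) > std::abs(a2)) std::swap(a1, a2);
          const size_t i = z + (size_t)nz * (y + (size_t)ny * x);
          l1[i] = a1; l2[i] = a2; l3[i] = a3;
          const double S = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3);
          if (S > smax) smax = S;
        }
    const double c = (cpar > 0) ? cpar : (smax > 0 ? 0.5 * smax : 1.0);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double a1 = l1[i], a2 = l2[i], a3 = l3[i];
      if (a2 >= 0 || a3 >= 0) continue; // bright tubes: both large eigvals < 0
      const double Ra = std::abs(a2) / std::abs(a3);
      const double Rb = std::abs(a1) / std::sqrt(std::abs(a2 * a3));
      const double S = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3);
      const double v = (1.0 - std::exp(-Ra * Ra / (2 * alpha * alpha))) *
                       std::exp(-Rb * Rb / (2 * beta * beta)) *
                       (1.0 - std::exp(-S * S / (2 * c * c)));
      if (v > out[i]) out[i] = v;
    }
  }
  return out;
}
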