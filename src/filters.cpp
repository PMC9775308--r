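#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are (z, y, x) with z fastest: idx = z + nz*(y + ny*x).
// All plane-wise filters use symmetric (reflect) padding.

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".median_filter_xy_cpp")]]
NumericVector median_filter_xy_cpp(NumericVector vol, IntegerVector dim, int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  if (radius <= 0) { std::copy(vol.begin(), vol.end(), out.begin()); return out; }
  const int w = 2 * radius + 1;
  std::vector<double> win(w * w);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        int k = 0;
        for (int dx = -radius; dx <= radius; ++dx) {
          const int xx = reflect(x + dx, nx);
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = reflect(y + dy, ny);
            win[k++] = vol[z + nz * (yy + ny * xx)];
          }
        }
        std::nth_element(win.begin(), win.begin() + (w * w) / 2, win.end());
        out[z + nz * (y + ny * x)] = win[(w * w) / 2];
      }
    }
  }
  return out;
}

// Grayscale erosion/dilation per XY plane with a structuring function given
// as offset lists (dy, dx) and heights h. Erosion: min(I(p+u) - h(u));
// dilation: max(I(p+u) + h(u)). Used to roll a ball under the surface.
static void gray_morph_plane(const double* in, double* out, int ny, int nx,
                             const std::vector<int>& dy, const std::vector<int>& dx,
                             const std::vector<double>& h, bool erode, int nzstride) {
  const size_t m = dy.size();
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double v = erode ? R_PosInf : R_NegInf;
      for (size_t k = 0; k < m; ++k) {
        const int yy = reflect(y + dy[k], ny);
        const int xx = reflect(x + dx[k], nx);
        const double val = in[(size_t)nzstride * (yy + (size_t)ny * xx)];
        if (erode) { double c = val - h[k]; if (c < v) v = c; }
        else       { double c = val + h[k]; if (c > v) v = c; }
      }
      out[(size_t)nzstride * (y + (size_t)ny * x)] = v;
    }
  }
}

// Plane-wise rolling-ball background: grayscale opening with a ball
// (hemisphere) structuring function of the given radius. Returns the
// background estimate; callers subtract and clip.
// [[Rcpp::export(name = ".rolling_ball_bg_cpp")]]
NumericVector rolling_ball_bg_cpp(NumericVector vol, IntegerVector dim, int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> dy, dx; std::vector<double> h;
  const double r2 = (double)radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b) {
      const double d2 = (double)a * a + (double)b * b;
      if (d2 <= r2) { dy.push_back(a); dx.push_back(b); h.push_back(std::sqrt(r2 - d2)); }
    }
  NumericVector out(vol.size());
  std::vector<double> plane_in(ny * nx), ero(ny * nx), bg(ny * nx);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        plane_in[y + (size_t)ny * x] = vol[z + nz * (y + ny * x)];
    gray_morph_plane(plane_in.data(), ero.data(), ny, nx, dy, dx, h, true, 1);
    gray_morph_plane(ero.data(), bg.data(), ny, nx, dy, dx, h, false, 1);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        out[z + nz * (y + ny * x)] = bg[y + (size_t)ny * x];
  }
  return out;
}

// Binary erosion/dilation per XY plane with a flat disk, reflect padding.
static void bin_morph_planes(const int* in, int* out, int nz, int ny, int nx,
                             const std::vector<int>& dy, const std::vector<int>& dx,
                             bool erode) {
  const size_t m = dy.size();
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int v = erode ? 1 : 0;
        for (size_t k = 0; k < m; ++k) {
          const int yy = reflect(y + dy[k], ny);
          const int xx = reflect(x + dx[k], nx);
          const int val = in[z + (size_t)nz * (yy + (size_t)ny * xx)];
          if (erode) { if (!val) { v = 0; break; } }
          else       { if (val)  { v = 1; break; } }
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = v;
      }
}

// op: sequence of 'c' (close) and/or 'o' (open), applied in order.
// [[Rcpp::export(name = ".binary_disk_morph_cpp")]]
LogicalVector binary_disk_morph_cpp(LogicalVector mask, IntegerVector dim, int radius,
                                    std::string ops) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out(mask.size());
  if (radius <= 0) { std::copy(mask.begin(), mask.end(), out.begin()); return out; }
  std::vector<int> dy, dx;
  const double r2 = (double)radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if ((double)a * a + (double)b * b <= r2) { dy.push_back(a); dx.push_back(b); }
  std::vector<int> cur(mask.size()), tmp(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) cur[i] = mask[i] ? 1 : 0;
  for (char op : ops) {
    if (op == 'c') {
      bin_morph_planes(cur.data(), tmp.data(), nz, ny, nx, dy, dx, false);
      bin_morph_planes(tmp.data(), cur.data(), nz, ny, nx, dy, dx, true);
    } else if (op == 'o') {
      bin_morph_planes(cur.data(), tmp.data(), nz, ny, nx, dy, dx, true);
      bin_morph_planes(tmp.data(), cur.data(), nz, ny, nx, dy, dx, false);
    }
  }
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = cur[i] != 0;
  return out;
}
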