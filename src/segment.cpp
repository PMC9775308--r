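#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// idx = z + nz*(y + ny*x)

// Hysteresis threshold: keep voxels >= low that are 26-connected to a voxel >= high.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalVector hysteresis_cpp(NumericVector vol, IntegerVector dim, double low, double high) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = vol.size();
  std::vector<char> state(n, 0); // 0 below low, 1 candidate, 2 accepted
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vol[i] >= high) { state[i] = 2; stack.push_back((int)i); }
    else if (vol[i] >= low) state[i] = 1;
  }
  while (!stack.empty()) {
    const int i = stack.back(); stack.pop_back();
    const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    for (int dx = -1; dx <= 1; ++dx) {
      const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          const int j = zz + nz * (yy + ny * xx);
          if (state[j] == 1) { state[j] = 2; stack.push_back(j); }
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = state[i] == 2;
  return out;
}

// Connected-component labels (26- or 6-connectivity), 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int i = stack.back(); stack.pop_back();
      const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
            if (connectivity == 6 &&
                (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
            const int j = zz + nz * (yy + ny * xx);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
    }
  }
  return lab;
}
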