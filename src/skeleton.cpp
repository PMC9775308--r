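#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Distance-ordered homotopic thinning to a curve skeleton.
// A voxel is deletable when it is a (26,6) simple point (removal preserves
// both foreground 26-topology and background 6-topology) and is not a curve
// endpoint (<= 1 foreground 26-neighbour). Voxels are processed in order of
// increasing distance-to-background so the centreline survives.

namespace {

struct NbTables {
  int off[27][3];          // (dz,dy,dx) for the 27 cube positions
  bool adj26[27][27];
  bool adj6[27][27];
  bool in18[27];           // 18-neighbourhood (excl. centre, excl. corners)
  bool face[27];           // the 6 face neighbours
  int centre;
  NbTables() {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          off[k][0] = dz; off[k][1] = dy; off[k][2] = dx;
          const int a = std::abs(dz) + std::abs(dy) + std::abs(dx);
          in18[k] = (a >= 1 && a <= 2);
          face[k] = (a == 1);
          if (a == 0) centre = k;
          ++k;
        }
    for (int i = 0; i < 27; ++i)
      for (int j = 0; j < 27; ++j) {
        const int az = std::abs(off[i][0] - off[j][0]);
        const int ay = std::abs(off[i][1] - off[j][1]);
        const int ax = std::abs(off[i][2] - off[j][2]);
        const int cheb = std::max(az, std::max(ay, ax));
        adj26[i][j] = (i != j) && cheb == 1;
        adj6[i][j] = (i != j) && (az + ay + ax) == 1;
      }
  }
};

const NbTables& tables() { static NbTables t; return t; }

// nb[27]: foreground flags of the 3x3x3 neighbourhood (centre included,
// assumed foreground). Out-of-volume positions must be passed as background.
bool is_simple(const bool nb[27]) {
  const NbTables& T = tables();
  // A: exactly one 26-component of foreground among the 26 neighbours
  bool seen[27] = {false};
  int compA = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == T.centre || !nb[s] || seen[s]) continue;
    ++compA;
    if (compA > 1) return false;
    std::vector<int> st{s};
    seen[s] = true;
    while (!st.empty()) {
      const int i = st.back(); st.pop_back();
      for (int j = 0; j < 27; ++j)
        if (j != T.centre && nb[j] && !seen[j] && T.adj26[i][j]) {
          seen[j] = true; st.push_back(j);
        }
    }
  }
  if (compA != 1) return false;
  // B: exactly one 6-component of background within the 18-neighbourhood
  // that touches a face neighbour
  bool seenB[27] = {false};
  int compB = 0;
  for (int s = 0; s < 27; ++s) {
    if (!T.in18[s] || nb[s] || seenB[s]) continue;
    bool touches = T.face[s];
    std::vector<int> st{s};
    seenB[s] = true;
    while (!st.empty()) {
      const int i = st.back(); st.pop_back();
      for (int j = 0; j < 27; ++j)
        if (T.in18[j] && !nb[j] && !seenB[j] && T.adj6[i][j]) {
          seenB[j] = true;
          if (T.face[j]) touches = true;
          st.push_back(j);
        }
    }
    if (touches) ++compB;
    if (compB > 1) return false;
  }
  return compB == 1;
}

} // namespace

// Distance-ordered thinning with directional sub-iterations. Distance
// levels are processed in increasing order; within a level, deletion
// sweeps cycle over the six face directions and only remove voxels whose
// background 6-neighbour lies in the sweep direction, so cross-sections
// peel symmetrically (a sequential tie order would otherwise consume
// even-diameter cores slice by slice along the axis). A voxel outside the
// volume counts as background for the topology test but does not make a
// voxel "exposed", so structures spanning the volume keep their full
// length. Curve endpoints (<= 1 foreground 26-neighbour) are preserved.
// [[Rcpp::export(name = ".thin_skeleton_cpp")]]
LogicalVector thin_skeleton_cpp(LogicalVector mask, IntegerVector dim, NumericVector dist) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;
  const NbTables& T = tables();

  auto gather = [&](int z, int y, int x, bool nb[27]) {
    for (int s = 0; s < 27; ++s) {
      const int zz = z + T.off[s][0], yy = y + T.off[s][1], xx = x + T.off[s][2];
      nb[s] = (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx) &&
              fg[zz + (size_t)nz * (yy + (size_t)ny * xx)];
    }
  };

  // remaining foreground indices, ordered by distance then array order
  std::vector<int> idxs;
  idxs.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i) if (fg[i]) idxs.push_back((int)i);
  std::stable_sort(idxs.begin(), idxs.end(),
                   [&](int a, int b) { return dist[a] < dist[b]; });

  // distance levels (unique values, ascending)
  std::vector<double> levels;
  for (int i : idxs)
    if (levels.empty() || dist[i] > levels.back() + 1e-9) levels.push_back(dist[i]);

  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool nb[27];
  // deletions within one sweep form an independent set (no two deleted
  // voxels 26-adjacent), so a deletion front cannot run along a thin
  // structure and consume it within a single sweep
  std::vector<int> del_stamp(n, -1);
  int sweep = 0;

  for (double L : levels) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int d = 0; d < 6; ++d) {
        ++sweep;
        for (int i : idxs) {
          if (!fg[i] || dist[i] > L + 1e-9) continue;
          const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
          const int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
          // exposed in direction d: in-volume background neighbour there
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (fg[zz + (size_t)nz * (yy + (size_t)ny * xx)]) continue;
          bool blocked = false;
          for (int s = 0; s < 27 && !blocked; ++s) {
            if (s == T.centre) continue;
            const int z2 = z + T.off[s][0], y2 = y + T.off[s][1], x2 = x + T.off[s][2];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
            if (del_stamp[z2 + (size_t)nz * (y2 + (size_t)ny * x2)] == sweep) blocked = true;
          }
          if (blocked) continue;
          gather(z, y, x, nb);
          int nn = 0;
          for (int s = 0; s < 27; ++s) if (s != T.centre && nb[s]) ++nn;
          if (nn <= 1) continue; // curve endpoint or isolated: keep
          if (!is_simple(nb)) continue;
          fg[i] = 0;
          del_stamp[i] = sweep;
          changed = true;
        }
      }
    }
    // compact the index list to the survivors
    std::vector<int> keep;
    keep.reserve(idxs.size());
    for (int i : idxs) if (fg[i]) keep.push_back(i);
    idxs.swap(keep);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}
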