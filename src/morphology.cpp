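// 3D binary-volume kernels used by the tomogram morphometry pipeline:
// 26-connected component labeling, exact Euclidean distance transform
// (Felzenszwalb & Huttenlocher separable lower envelope), and sequential
// curve thinning that deletes simple border points while preserving
// endpoints (Malandain-Bertrand simple-point characterization).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int z0 = 0; z0 < nz; ++z0) for (int y0 = 0; y0 < ny; ++y0)
    for (int x0 = 0; x0 < nx; ++x0) {
      int i0 = idx3(x0, y0, z0, nx, ny);
      if (!mask[i0] || lab[i0]) continue;
      ++next;
      lab[i0] = next;
      stack.clear();
      stack.push_back(i0);
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int x = i % nx, y = (i / nx) % ny, zz = i / (nx * ny);
        for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = zz + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            int j = idx3(X, Y, Z, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
      }
    }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared distance transform (lower envelope of parabolas)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; zb[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= zb[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    bool any = false;
    for (int x = 0; x < nx; ++x) { f[x] = g[idx3(x, y, z, nx, ny)]; if (f[x] != INF) any = true; }
    if (!any) continue;
    dt1d(f, d, nx);
    for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
  }
  // along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    bool any = false;
    for (int y = 0; y < ny; ++y) { f[y] = g[idx3(x, y, z, nx, ny)]; if (f[y] != INF) any = true; }
    if (!any) continue;
    dt1d(f, d, ny);
    for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
  }
  // along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    bool any = false;
    for (int z = 0; z < nz; ++z) { f[z] = g[idx3(x, y, z, nx, ny)]; if (f[z] != INF) any = true; }
    if (!any) continue;
    dt1d(f, d, nz);
    for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::isinf(g[i]) ? NA_REAL : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// --- simple-point machinery on the 3x3x3 neighborhood ----------------------

// nb[27]: occupancy of the 3x3x3 block, index = (dx+1) + 3*(dy+1) + 9*(dz+1),
// center at 13.

static const int NB_OFF[27][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

static inline bool adj26(int a, int b) {
  int dx = NB_OFF[a][0] - NB_OFF[b][0];
  int dy = NB_OFF[a][1] - NB_OFF[b][1];
  int dz = NB_OFF[a][2] - NB_OFF[b][2];
  return (a != b) && std::abs(dx) <= 1 && std::abs(dy) <= 1 && std::abs(dz) <= 1;
}

static inline bool adj6(int a, int b) {
  int dx = NB_OFF[a][0] - NB_OFF[b][0];
  int dy = NB_OFF[a][1] - NB_OFF[b][1];
  int dz = NB_OFF[a][2] - NB_OFF[b][2];
  return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
}

// number of 26-connected components of foreground in N26 (center excluded)
static int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> st; st.push_back(s); seen[s] = true;
    while (!st.empty()) {
      int a = st.back(); st.pop_back();
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || !nb[b] || seen[b]) continue;
        if (adj26(a, b)) { seen[b] = true; st.push_back(b); }
      }
    }
  }
  return comps;
}

// number of 6-connected components of background restricted to the
// 18-neighborhood that are 6-adjacent to the center
static int bg_components6(const bool nb[27]) {
  bool in18[27];
  for (int s = 0; s < 27; ++s) {
    int m = std::abs(NB_OFF[s][0]) + std::abs(NB_OFF[s][1]) + std::abs(NB_OFF[s][2]);
    in18[s] = (m == 1 || m == 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    if (!adj6(s, 13)) continue;  // seed only from face neighbors of center
    ++comps;
    std::vector<int> st; st.push_back(s); seen[s] = true;
    while (!st.empty()) {
      int a = st.back(); st.pop_back();
      for (int b = 0; b < 27; ++b) {
        if (!in18[b] || nb[b] || seen[b]) continue;
        if (adj6(a, b)) { seen[b] = true; st.push_back(b); }
      }
    }
  }
  return comps;
}

static inline void fill_nb(const std::vector<char>& vol, int x, int y, int z,
                           int nx, int ny, int nz, bool nb[27]) {
  for (int s = 0; s < 27; ++s) {
    int X = x + NB_OFF[s][0], Y = y + NB_OFF[s][1], Z = z + NB_OFF[s][2];
    nb[s] = (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz) &&
            vol[idx3(X, Y, Z, nx, ny)];
  }
}

static inline int fg_neighbors(const bool nb[27]) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++c;
  return c;
}

static inline bool is_simple(const bool nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> vol(n);
  for (int i = 0; i < n; ++i) vol[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool nb[27];
  bool changed = true;
  std::vector<int> cand;
  std::vector<int> cand_fgn;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      cand_fgn.clear();
      for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!vol[i]) continue;
          int X = x + dirs[d][0], Y = y + dirs[d][1], Z = z + dirs[d][2];
          bool border = !(X >= 0 && X < nx && Y >= 0 && Y < ny &&
                          Z >= 0 && Z < nz) ||
                        !vol[idx3(X, Y, Z, nx, ny)];
          if (!border) continue;
          fill_nb(vol, x, y, z, nx, ny, nz, nb);
          int fgn = fg_neighbors(nb);
          if (fgn <= 1) continue;  // endpoint: preserve
          if (is_simple(nb)) { cand.push_back(i); cand_fgn.push_back(fgn); }
        }
      // sequential re-check so deletions cannot break topology; a candidate
      // whose neighborhood changed since collection may only be deleted if
      // the object is still at least two voxels thick along d (foreground
      // on the opposite side) -- without this guard the sequential pass can
      // unravel a thin slab or curve end-first within a single subiteration
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        fill_nb(vol, x, y, z, nx, ny, nz, nb);
        int fgn = fg_neighbors(nb);
        if (fgn <= 1) continue;
        if (fgn != cand_fgn[k]) {
          int Xo = x - dirs[d][0], Yo = y - dirs[d][1], Zo = z - dirs[d][2];
          bool opp_fg = (Xo >= 0 && Xo < nx && Yo >= 0 && Yo < ny &&
                         Zo >= 0 && Zo < nz) &&
                        vol[idx3(Xo, Yo, Zo, nx, ny)];
          if (!opp_fg) continue;
        }
        if (is_simple(nb)) { vol[i] = 0; changed = true; }
      }
    }
  }

  // final cleanup: the cascade guard can leave locally 2-wide skeleton
  // remnants; voxels with >= 3 neighbors are not curve interiors and can be
  // deleted whenever simple (curve voxels have exactly 2 and are untouched)
  changed = true;
  while (changed) {
    changed = false;
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!vol[i]) continue;
        fill_nb(vol, x, y, z, nx, ny, nz, nb);
        if (fg_neighbors(nb) < 3) continue;
        if (is_simple(nb)) { vol[i] = 0; changed = true; }
      }
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vol[i] != 0;
  out.attr("dim") = dim;
  return out;
}
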