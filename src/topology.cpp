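// 3D digital topology primitives on the object-26 / background-6 connectivity
// pair: topological numbers, simple-point test, Malandain-Bertrand voxel
// classification, connected component labelling.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include "topo.h"
using namespace Rcpp;

// Local 3x3x3 indexing: li = (dx+1) + 3*(dy+1) + 9*(dz+1), center li = 13.
// Matches the memory order of an R 3x3x3 logical array.

static inline int lidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// Topological numbers of a 27-cell configuration (center occupancy ignored):
//  Cstar: number of 26-components of the object within the 26-neighbourhood
//         (all are 26-adjacent to the center by construction).
//  Cbar : number of 6-components of the background within the 18-neighbourhood
//         that contain at least one 6-neighbour of the center.
static void topo_numbers_local(const bool occ[27], int &cstar, int &cbar) {
  // --- Cstar: 26-components of object cells among the 26 neighbours ---
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  cstar = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !occ[i] || comp[i] >= 0) continue;
    // BFS over object cells, 26-adjacency (Chebyshev distance 1)
    std::queue<int> q;
    comp[i] = cstar;
    q.push(i);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1)
              continue;
            int n = lidx(nx, ny, nz);
            if (n == 13 || n == c || !occ[n] || comp[n] >= 0) continue;
            comp[n] = cstar;
            q.push(n);
          }
    }
    ++cstar;
  }

  // --- Cbar: 6-components of background in N18, 6-adjacent to center ---
  // N18: cells with |dx|+|dy|+|dz| <= 2, excluding center.
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int s = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (s >= 1 && s <= 2);
  }
  int bcomp[27];
  for (int i = 0; i < 27; ++i) bcomp[i] = -1;
  int ncomp = 0;
  static const int face_d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  std::vector<bool> touches;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || occ[i] || bcomp[i] >= 0) continue;
    bool touch = false;
    std::queue<int> q;
    bcomp[i] = ncomp;
    q.push(i);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      if (std::abs(cx) + std::abs(cy) + std::abs(cz) == 1) touch = true;
      for (int k = 0; k < 6; ++k) {
        int nx = cx + face_d[k][0], ny = cy + face_d[k][1], nz = cz + face_d[k][2];
        if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1) continue;
        int n = lidx(nx, ny, nz);
        if (!in18[n] || n == 13 || occ[n] || bcomp[n] >= 0) continue;
        bcomp[n] = ncomp;
        q.push(n);
      }
    }
    touches.push_back(touch);
    ++ncomp;
  }
  cbar = 0;
  for (size_t k = 0; k < touches.size(); ++k)
    if (touches[k]) ++cbar;
}

// [[Rcpp::export]]
IntegerVector topo_numbers_config(LogicalVector config) {
  if (config.size() != 27) stop("config must be a 3x3x3 logical array");
  bool occ[27];
  for (int i = 0; i < 27; ++i) occ[i] = config[i] == TRUE;
  int cs, cb;
  topo_numbers_local(occ, cs, cb);
  return IntegerVector::create(cs, cb);
}

static inline bool inb(int x, int n) { return x >= 0 && x < n; }

static void fill_local(const int *obj, int nx, int ny, int nz,
                       int x, int y, int z, bool occ[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = inb(xx, nx) && inb(yy, ny) && inb(zz, nz) &&
                 obj[xx + (size_t)nx * (yy + (size_t)ny * zz)] != 0;
        occ[lidx(dx, dy, dz)] = v;
      }
}

// Topological numbers (Cstar, Cbar) for each queried voxel of a 3D object.
// vox is an n x 3 matrix of 0-based voxel indices.
// [[Rcpp::export]]
IntegerMatrix topo_numbers_grid(IntegerVector obj, IntegerVector dim,
                                IntegerMatrix vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *o = INTEGER(obj);
  int n = vox.nrow();
  IntegerMatrix out(n, 2);
  bool occ[27];
  for (int i = 0; i < n; ++i) {
    fill_local(o, nx, ny, nz, vox(i, 0), vox(i, 1), vox(i, 2), occ);
    int cs, cb;
    topo_numbers_local(occ, cs, cb);
    out(i, 0) = cs;
    out(i, 1) = cb;
  }
  return out;
}

bool simple_point_local(const bool occ[27]) {
  int cs, cb;
  topo_numbers_local(occ, cs, cb);
  return cs == 1 && cb == 1;
}

// [[Rcpp::export]]
LogicalVector simple_point_config(LogicalMatrix configs) {
  // each row: 27 cells of a 3x3x3 configuration (column-major local order)
  int n = configs.nrow();
  if (configs.ncol() != 27) stop("configs must have 27 columns");
  LogicalVector out(n);
  bool occ[27];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 27; ++j) occ[j] = configs(i, j) == TRUE;
    out[i] = simple_point_local(occ);
  }
  return out;
}

// Malandain-Bertrand classes from (Cstar, Cbar):
// 1 interior (Cbar==0), 2 isolated (Cstar==0), 3 border (1,1), 4 curve (2,1),
// 5 curves (>2,1), 6 surface (1,2), 7 surface-curve (>=2,2),
// 8 surfaces (1,>2), 9 surfaces-curve (>=2,>2)
int topo_class_from_numbers(int cs, int cb) {
  if (cb == 0) return 1;
  if (cs == 0) return 2;
  if (cb == 1) {
    if (cs == 1) return 3;
    if (cs == 2) return 4;
    return 5;
  }
  if (cb == 2) return (cs == 1) ? 6 : 7;
  return (cs == 1) ? 8 : 9;
}

// [[Rcpp::export]]
IntegerVector classify_voxels_cpp(IntegerVector obj, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *o = INTEGER(obj);
  size_t ntot = (size_t)nx * ny * nz;
  IntegerVector out(ntot, 0);
  bool occ[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t id = x + (size_t)nx * (y + (size_t)ny * z);
        if (!o[id]) continue;
        fill_local(o, nx, ny, nz, x, y, z, occ);
        int cs, cb;
        topo_numbers_local(occ, cs, cb);
        out[id] = topo_class_from_numbers(cs, cb);
      }
  return out;
}

// Connected component labelling; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector obj, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *o = INTEGER(obj);
  size_t ntot = (size_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<std::array<int,3>> nbs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && s != 1) continue;
        nbs.push_back({dx, dy, dz});
      }
  int ncomp = 0;
  std::queue<size_t> q;
  for (size_t start = 0; start < ntot; ++start) {
    if (!o[start] || lab[start]) continue;
    ++ncomp;
    lab[start] = ncomp;
    q.push(start);
    while (!q.empty()) {
      size_t c = q.front(); q.pop();
      int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
      for (auto &d : nbs) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (!inb(xx, nx) || !inb(yy, ny) || !inb(zz, nz)) continue;
        size_t n = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (o[n] && !lab[n]) { lab[n] = ncomp; q.push(n); }
      }
    }
  }
  lab.attr("ncomp") = ncomp;
  return lab;
}
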