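// Homotopic (simple-point) erosion machinery: chamfer distance transform,
// collapse of an enclosing ellipsoid onto a mask, well-composed repair, and
// the curvature-gated ordered thinning that produces the sulcal skeleton.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include "topo.h"
using namespace Rcpp;

static inline bool inb(int x, int n) { return x >= 0 && x < n; }

// Chamfer distance (mm) from a voxel set, two-pass over the 26-neighbourhood
// with anisotropic step costs. dist = 0 inside the set.
// [[Rcpp::export]]
NumericVector chamfer_distance_cpp(IntegerVector set, IntegerVector dim,
                                   NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  const int *s = INTEGER(set);
  NumericVector dist(ntot);
  const double INF = 1e30;
  for (size_t i = 0; i < ntot; ++i) dist[i] = s[i] ? 0.0 : INF;

  std::vector<std::array<int,3>> offs;
  std::vector<double> cost;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs.push_back({dx, dy, dz});
        cost.push_back(std::sqrt(dx * dx * spacing[0] * spacing[0] +
                                 dy * dy * spacing[1] * spacing[1] +
                                 dz * dz * spacing[2] * spacing[2]));
      }
  // forward pass: neighbours with lower linear index; backward: higher
  for (int pass = 0; pass < 2; ++pass) {
    bool fwd = pass == 0;
    for (long zz = 0; zz < nz; ++zz) {
      int z = fwd ? zz : nz - 1 - zz;
      for (long yy = 0; yy < ny; ++yy) {
        int y = fwd ? yy : ny - 1 - yy;
        for (long xx = 0; xx < nx; ++xx) {
          int x = fwd ? xx : nx - 1 - xx;
          size_t id = x + (size_t)nx * (y + (size_t)ny * z);
          double d = dist[id];
          if (d == 0.0) continue;
          for (size_t k = 0; k < offs.size(); ++k) {
            int ddx = offs[k][0], ddy = offs[k][1], ddz = offs[k][2];
            long lin = ddx + (long)nx * (ddy + (long)ny * ddz);
            if (fwd ? (lin >= 0) : (lin <= 0)) continue;
            int nx2 = x + ddx, ny2 = y + ddy, nz2 = z + ddz;
            if (!inb(nx2, nx) || !inb(ny2, ny) || !inb(nz2, nz)) continue;
            size_t nid = nx2 + (size_t)nx * (ny2 + (size_t)ny * nz2);
            double cand = dist[nid] + cost[k];
            if (cand < d) d = cand;
          }
          dist[id] = d;
        }
      }
    }
  }
  return dist;
}

struct QItem {
  double p1, p2;
  size_t idx;
};
struct QCmpMax {  // max-heap on p1 then p2 then smaller index first
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.p1 != b.p1) return a.p1 < b.p1;
    if (a.p2 != b.p2) return a.p2 < b.p2;
    return a.idx > b.idx;
  }
};
struct QCmpMin {  // min-heap on p1 then p2 then smaller index first
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.p1 != b.p1) return a.p1 > b.p1;
    if (a.p2 != b.p2) return a.p2 > b.p2;
    return a.idx > b.idx;
  }
};

static const int FACE6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

static bool is_boundary6(const std::vector<int> &obj, int nx, int ny, int nz,
                         size_t id) {
  int x = id % nx, y = (id / nx) % ny, z = id / ((size_t)nx * ny);
  for (int k = 0; k < 6; ++k) {
    int xx = x + FACE6[k][0], yy = y + FACE6[k][1], zz = z + FACE6[k][2];
    if (!inb(xx, nx) || !inb(yy, ny) || !inb(zz, nz)) return true;
    if (!obj[xx + (size_t)nx * (yy + (size_t)ny * zz)]) return true;
  }
  return false;
}

// Collapse an enclosing binary set (e.g. a filled ellipsoid) onto a mask by
// removing, farthest-from-mask first, voxels outside the mask whose removal
// preserves topology (object 26 / background 6). Handles in the mask end up
// plugged, cavities filled; the result is homotopic to the initial set.
// [[Rcpp::export]]
IntegerVector collapse_to_mask_cpp(IntegerVector init, IntegerVector mask,
                                   IntegerVector dim, NumericVector priority) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<int> obj(ntot);
  for (size_t i = 0; i < ntot; ++i) obj[i] = init[i] != 0;
  const int *m = INTEGER(mask);

  std::priority_queue<QItem, std::vector<QItem>, QCmpMax> pq;
  for (size_t i = 0; i < ntot; ++i)
    if (obj[i] && !m[i] && is_boundary6(obj, nx, ny, nz, i))
      pq.push({priority[i], 0.0, i});

  bool occ[27];
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    size_t id = it.idx;
    if (!obj[id] || m[id]) continue;
    if (!is_boundary6(obj, nx, ny, nz, id)) continue;
    int x = id % nx, y = (id / nx) % ny, z = id / ((size_t)nx * ny);
    topo_fill_local(obj.data(), nx, ny, nz, x, y, z, occ);
    if (!simple_point_local(occ)) continue;  // may become simple later
    obj[id] = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (!inb(xx, nx) || !inb(yy, ny) || !inb(zz, nz)) continue;
          size_t nid = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (obj[nid] && !m[nid]) pq.push({priority[nid], 0.0, nid});
        }
  }
  IntegerVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = obj[i];
  return out;
}

// Is it topologically safe to ADD voxel v (i.e. v is a simple point of
// obj + v)? Used by the well-composed repair.
static bool addable(const std::vector<int> &obj, int nx, int ny, int nz,
                    size_t id) {
  int x = id % nx, y = (id / nx) % ny, z = id / ((size_t)nx * ny);
  bool occ[27];
  topo_fill_local(obj.data(), nx, ny, nz, x, y, z, occ);
  return simple_point_local(occ);
}

// Repair critical (non-well-composed) configurations by adding voxels whose
// addition is a simple-point operation. On a well-composed set the voxel
// boundary is a 2-manifold and its genus equals the digital 26/6 genus.
// [[Rcpp::export]]
IntegerVector well_compose_cpp(IntegerVector setv, IntegerVector dim,
                               int max_pass = 20) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<int> obj(ntot);
  for (size_t i = 0; i < ntot; ++i) obj[i] = setv[i] != 0;

  auto at = [&](int x, int y, int z) -> int {
    if (!inb(x, nx) || !inb(y, ny) || !inb(z, nz)) return 0;
    return obj[x + (size_t)nx * (y + (size_t)ny * z)];
  };
  auto id3 = [&](int x, int y, int z) -> size_t {
    return x + (size_t)nx * (y + (size_t)ny * z);
  };

  for (int pass = 0; pass < max_pass; ++pass) {
    long fixed = 0, found = 0;
    // 2x2 squares in the three axis planes: diagonal object pair with
    // anti-diagonal background pair is critical.
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // squares with corners (x,y,z) + spans along two of the axes
          const int spans[3][2][3] = {{{1,0,0},{0,1,0}},
                                      {{1,0,0},{0,0,1}},
                                      {{0,1,0},{0,0,1}}};
          for (int s = 0; s < 3; ++s) {
            int ax = spans[s][0][0], ay = spans[s][0][1], az = spans[s][0][2];
            int bx = spans[s][1][0], by = spans[s][1][1], bz = spans[s][1][2];
            if (!inb(x + ax + bx, nx) || !inb(y + ay + by, ny) ||
                !inb(z + az + bz, nz))
              continue;
            int v00 = at(x, y, z);
            int v10 = at(x + ax, y + ay, z + az);
            int v01 = at(x + bx, y + by, z + bz);
            int v11 = at(x + ax + bx, y + ay + by, z + az + bz);
            bool critA = v00 && v11 && !v10 && !v01;
            bool critB = v10 && v01 && !v00 && !v11;
            if (!critA && !critB) continue;
            ++found;
            size_t c1 = critA ? id3(x + ax, y + ay, z + az) : id3(x, y, z);
            size_t c2 = critA ? id3(x + bx, y + by, z + bz)
                              : id3(x + ax + bx, y + ay + by, z + az + bz);
            if (addable(obj, nx, ny, nz, c1)) { obj[c1] = 1; ++fixed; }
            else if (addable(obj, nx, ny, nz, c2)) { obj[c2] = 1; ++fixed; }
          }
        }
    // 2x2x2 cubes: exactly two antipodal object corners (rest background),
    // or exactly two antipodal background corners (rest object).
    for (int z = 0; z + 1 < nz; ++z)
      for (int y = 0; y + 1 < ny; ++y)
        for (int x = 0; x + 1 < nx; ++x) {
          int v[8];
          int cnt = 0;
          for (int k = 0; k < 8; ++k) {
            v[k] = at(x + (k & 1), y + ((k >> 1) & 1), z + ((k >> 2) & 1));
            cnt += v[k];
          }
          bool crit = false;
          int add_k = -1;
          if (cnt == 2) {
            for (int k = 0; k < 4; ++k)
              if (v[k] && v[7 - k]) { crit = true; }
            if (crit) {  // bridge via a face neighbour of one object corner
              for (int k = 0; k < 8 && add_k < 0; ++k)
                if (!v[k]) add_k = k;
            }
          } else if (cnt == 6) {
            for (int k = 0; k < 4; ++k)
              if (!v[k] && !v[7 - k]) { crit = true; add_k = k; }
          }
          if (!crit) continue;
          ++found;
          // try every background corner of the cube, in fixed order
          for (int k = 0; k < 8; ++k) {
            if (v[k]) continue;
            size_t cid = id3(x + (k & 1), y + ((k >> 1) & 1), z + ((k >> 2) & 1));
            if (addable(obj, nx, ny, nz, cid)) { obj[cid] = 1; ++fixed; break; }
          }
        }
    if (found == 0) break;
    if (fixed == 0) break;  // nothing repairable left
  }
  IntegerVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = obj[i];
  return out;
}

// Ordered homotopic thinning of the GM+CSF union with an embedded watershed.
//  uni   : binary union
//  frozen: voxels never removed (hull + catchment-basin seeds)
//  prio  : primary removal order (distance from the inner WM-adjacent
//          boundary; closest removed first)
//  curvH : mean curvature (1/mm); a voxel is eligible only if H < h_thresh
//  basin : watershed labels (>0 on seed clusters, 0 elsewhere); removal water
//          inherits labels, and a voxel whose removal would merge water from
//          two distinct basins is frozen as a ridge.
// Returns state: 0 removed/background, 1 remaining, 2 frozen (hull/seed/ridge)
// with attribute "order": 1-based linear indices in removal order.
// [[Rcpp::export]]
IntegerVector skeletonize_cpp(IntegerVector uni, IntegerVector frozen,
                              NumericVector prio, NumericVector curvH,
                              double h_thresh, IntegerVector basin,
                              IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<int> obj(ntot), frz(ntot);
  std::vector<int> water(ntot, 0);
  for (size_t i = 0; i < ntot; ++i) {
    obj[i] = uni[i] != 0;
    frz[i] = frozen[i] != 0;
    if (basin[i] > 0) water[i] = basin[i];
  }

  std::priority_queue<QItem, std::vector<QItem>, QCmpMin> pq;
  for (size_t i = 0; i < ntot; ++i)
    if (obj[i] && !frz[i] && is_boundary6(obj, nx, ny, nz, i))
      pq.push({prio[i], curvH[i], i});

  std::vector<int> order;
  bool occ[27];
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    size_t id = it.idx;
    if (!obj[id] || frz[id]) continue;
    if (!is_boundary6(obj, nx, ny, nz, id)) continue;
    if (curvH[id] >= h_thresh) continue;  // convex edge: not erodible
    if (prio[id] > 1e29) continue;  // unreachable from the erosion front
    int x = id % nx, y = (id / nx) % ny, z = id / ((size_t)nx * ny);
    topo_fill_local(obj.data(), nx, ny, nz, x, y, z, occ);
    if (!simple_point_local(occ)) continue;  // retained: medial-sheet voxel
    // watershed: collect water labels among 26-neighbours (removed voxels
    // and seed voxels carry labels)
    int lab = 0;
    bool ridge = false;
    for (int dz = -1; dz <= 1 && !ridge; ++dz)
      for (int dy = -1; dy <= 1 && !ridge; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (!inb(xx, nx) || !inb(yy, ny) || !inb(zz, nz)) continue;
          size_t nid = xx + (size_t)nx * (yy + (size_t)ny * zz);
          int wl = water[nid];
          if (wl > 0 && obj[nid] && !frz[nid]) wl = 0;  // only water/seeds
          if (wl > 0) {
            if (lab == 0) lab = wl;
            else if (lab != wl) { ridge = true; break; }
          }
        }
    if (ridge) { frz[id] = 1; continue; }
    obj[id] = 0;
    water[id] = lab;
    order.push_back((int)(id + 1));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (!inb(xx, nx) || !inb(yy, ny) || !inb(zz, nz)) continue;
          size_t nid = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (obj[nid] && !frz[nid]) pq.push({prio[nid], curvH[nid], nid});
        }
  }
  IntegerVector out(ntot);
  for (size_t i = 0; i < ntot; ++i)
    out[i] = obj[i] ? (frz[i] ? 2 : 1) : 0;
  out.attr("order") = IntegerVector(order.begin(), order.end());
  return out;
}
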