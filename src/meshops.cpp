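// Mesh machinery: exact voxel-boundary surface extraction, edge-collapse
// decimation with link-condition and normal-flip guards, exact point-triangle
// distance queries with a uniform spatial grid, triangle-triangle
// intersection counting, self-proximity detection, and point location on a
// spherical triangulation.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <set>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- boundary --

// Extract the boundary surface of a binary voxel set as a welded triangle
// mesh in voxel coordinates (voxel centers at integers, faces at half-
// integers). Outward orientation. On a well-composed set this is a closed
// 2-manifold.
// [[Rcpp::export]]
List boundary_mesh_cpp(IntegerVector obj, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *o = INTEGER(obj);
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return o[x + (size_t)nx * (y + (size_t)ny * z)];
  };
  std::unordered_map<int64_t, int> vmap;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;
  auto vid = [&](double x, double y, double z) -> int {
    int64_t ix = (int64_t)std::llround(2 * x) + 2;
    int64_t iy = (int64_t)std::llround(2 * y) + 2;
    int64_t iz = (int64_t)std::llround(2 * z) + 2;
    int64_t key = ix + 4096 * (iy + 4096 * iz);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)VX.size();
    vmap[key] = id;
    VX.push_back(x); VY.push_back(y); VZ.push_back(z);
    return id;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!at(x, y, z)) continue;
        for (int axis = 0; axis < 3; ++axis)
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            int d[3] = {0, 0, 0};
            d[axis] = sgn;
            if (at(x + d[0], y + d[1], z + d[2])) continue;
            // face center
            double c[3] = {x + 0.5 * d[0], y + 0.5 * d[1], z + 0.5 * d[2]};
            int ia = (sgn > 0) ? (axis + 1) % 3 : (axis + 2) % 3;
            int ib = (sgn > 0) ? (axis + 2) % 3 : (axis + 1) % 3;
            double q[4][3];
            static const double sa[4] = {-0.5, 0.5, 0.5, -0.5};
            static const double sb[4] = {-0.5, -0.5, 0.5, 0.5};
            for (int k = 0; k < 4; ++k) {
              q[k][0] = c[0]; q[k][1] = c[1]; q[k][2] = c[2];
              q[k][ia] += sa[k];
              q[k][ib] += sb[k];
            }
            int i0 = vid(q[0][0], q[0][1], q[0][2]);
            int i1 = vid(q[1][0], q[1][1], q[1][2]);
            int i2 = vid(q[2][0], q[2][1], q[2][2]);
            int i3 = vid(q[3][0], q[3][1], q[3][2]);
            F.push_back(i0); F.push_back(i1); F.push_back(i2);
            F.push_back(i0); F.push_back(i2); F.push_back(i3);
          }
      }
  int nv = (int)VX.size(), nf = (int)F.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = VX[i]; V(i, 1) = VY[i]; V(i, 2) = VZ[i];
  }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = F[3 * i] + 1; Fm(i, 1) = F[3 * i + 1] + 1;
    Fm(i, 2) = F[3 * i + 2] + 1;  // 1-based for R
  }
  return List::create(_["vertices"] = V, _["triangles"] = Fm);
}

// -------------------------------------------------------------- decimation --

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// Edge-collapse decimation, shortest edge first, midpoint placement.
// Collapses only when the link condition holds and no incident face flips.
// [[Rcpp::export]]
List decimate_cpp(NumericMatrix Vin, IntegerMatrix Fin, int target) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<Vec3> V(nv);
  for (int i = 0; i < nv; ++i) V[i] = {Vin(i, 0), Vin(i, 1), Vin(i, 2)};
  std::vector<std::array<int, 3>> F(nf);
  for (int i = 0; i < nf; ++i)
    F[i] = {Fin(i, 0) - 1, Fin(i, 1) - 1, Fin(i, 2) - 1};
  std::vector<bool> valive(nv, true), falive(nf, true);
  std::vector<std::set<int>> vf(nv);  // vertex -> incident faces
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) vf[F[i][k]].insert(i);

  auto neighbors = [&](int u) {
    std::set<int> nb;
    for (int f : vf[u])
      if (falive[f])
        for (int k = 0; k < 3; ++k)
          if (F[f][k] != u) nb.insert(F[f][k]);
    return nb;
  };
  auto elen = [&](int u, int v) { return vnorm(vsub(V[u], V[v])); };

  typedef std::tuple<double, int, int> E;  // (length, u, v) u<v
  std::priority_queue<E, std::vector<E>, std::greater<E>> pq;
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int u = F[i][k], v = F[i][(k + 1) % 3];
      if (u < v) pq.push(E(elen(u, v), u, v));
    }

  int alive = nv;
  while (alive > target && !pq.empty()) {
    E e = pq.top(); pq.pop();
    double len = std::get<0>(e);
    int u = std::get<1>(e), v = std::get<2>(e);
    if (!valive[u] || !valive[v]) continue;
    if (std::fabs(elen(u, v) - len) > 1e-12) continue;  // stale entry
    // shared faces
    std::vector<int> shared;
    for (int f : vf[u])
      if (falive[f] && vf[v].count(f)) shared.push_back(f);
    if (shared.size() != 2) continue;  // boundary or non-manifold: skip
    // link condition: common neighbours must be exactly the 2 opposite verts
    std::set<int> nu = neighbors(u), nvv = neighbors(v), common;
    std::set_intersection(nu.begin(), nu.end(), nvv.begin(), nvv.end(),
                          std::inserter(common, common.begin()));
    if (common.size() != 2) continue;
    // tetrahedron guard: collapsing an edge of a 4-vertex closed mesh
    if (nu.size() <= 3 || nvv.size() <= 3) continue;
    Vec3 mid = {(V[u].x + V[v].x) / 2, (V[u].y + V[v].y) / 2,
                (V[u].z + V[v].z) / 2};
    // normal-flip / degeneracy guard over surviving incident faces
    bool ok = true;
    std::vector<int> affected;
    for (int f : vf[u]) if (falive[f]) affected.push_back(f);
    for (int f : vf[v]) if (falive[f] && !vf[u].count(f)) affected.push_back(f);
    for (int f : affected) {
      bool isShared = false;
      for (int s : shared) if (f == s) isShared = true;
      if (isShared) continue;
      Vec3 a = V[F[f][0]], b = V[F[f][1]], c = V[F[f][2]];
      Vec3 n0 = vcross(vsub(b, a), vsub(c, a));
      Vec3 a2 = (F[f][0] == u || F[f][0] == v) ? mid : a;
      Vec3 b2 = (F[f][1] == u || F[f][1] == v) ? mid : b;
      Vec3 c2 = (F[f][2] == u || F[f][2] == v) ? mid : c;
      Vec3 n1 = vcross(vsub(b2, a2), vsub(c2, a2));
      if (vnorm(n1) < 1e-14 || vdot(n0, n1) <= 0) { ok = false; break; }
    }
    if (!ok) continue;
    // commit: u absorbs v at midpoint
    V[u] = mid;
    for (int f : shared) {
      falive[f] = false;
      for (int k = 0; k < 3; ++k) vf[F[f][k]].erase(f);
    }
    for (int f : std::vector<int>(vf[v].begin(), vf[v].end())) {
      if (!falive[f]) { vf[v].erase(f); continue; }
      for (int k = 0; k < 3; ++k)
        if (F[f][k] == v) F[f][k] = u;
      vf[u].insert(f);
      vf[v].erase(f);
    }
    valive[v] = false;
    --alive;
    for (int w : neighbors(u)) {
      int a = std::min(u, w), b = std::max(u, w);
      pq.push(E(elen(a, b), a, b));
    }
  }
  // compact
  std::vector<int> remap(nv, -1);
  int nv2 = 0;
  for (int i = 0; i < nv; ++i)
    if (valive[i]) remap[i] = nv2++;
  NumericMatrix Vout(nv2, 3);
  for (int i = 0; i < nv; ++i)
    if (valive[i]) {
      Vout(remap[i], 0) = V[i].x;
      Vout(remap[i], 1) = V[i].y;
      Vout(remap[i], 2) = V[i].z;
    }
  int nf2 = 0;
  for (int i = 0; i < nf; ++i)
    if (falive[i]) ++nf2;
  IntegerMatrix Fout(nf2, 3);
  int r = 0;
  for (int i = 0; i < nf; ++i)
    if (falive[i]) {
      for (int k = 0; k < 3; ++k) Fout(r, k) = remap[F[i][k]] + 1;
      ++r;
    }
  return List::create(_["vertices"] = Vout, _["triangles"] = Fout,
                      _["achieved"] = nv2);
}

// --------------------------------------------------- point-triangle queries --

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
static Vec3 closest_on_tri(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                           const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    return {a.x + t * ab.x, a.y + t * ab.y, a.z + t * ab.z};
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    return {a.x + t * ac.x, a.y + t * ac.y, a.z + t * ac.z};
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 bc = vsub(c, b);
    return {b.x + t * bc.x, b.y + t * bc.y, b.z + t * bc.z};
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  return {a.x + ab.x * vv + ac.x * ww, a.y + ab.y * vv + ac.y * ww,
          a.z + ab.z * vv + ac.z * ww};
}

struct TriGrid {
  double x0, y0, z0, cell;
  int gx, gy, gz;
  std::vector<std::vector<int>> cells;
  int cid(int i, int j, int k) const { return i + gx * (j + gy * k); }
};

static TriGrid build_grid(const std::vector<Vec3> &V,
                          const std::vector<std::array<int, 3>> &F) {
  TriGrid g;
  double xmin = 1e30, ymin = 1e30, zmin = 1e30;
  double xmax = -1e30, ymax = -1e30, zmax = -1e30;
  double edge_sum = 0;
  for (auto &f : F) {
    for (int k = 0; k < 3; ++k) {
      const Vec3 &p = V[f[k]];
      xmin = std::min(xmin, p.x); xmax = std::max(xmax, p.x);
      ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
      zmin = std::min(zmin, p.z); zmax = std::max(zmax, p.z);
    }
    edge_sum += vnorm(vsub(V[f[1]], V[f[0]]));
  }
  double cell = std::max(edge_sum / std::max((size_t)1, F.size()), 1e-6) * 2.0;
  g.cell = cell;
  g.x0 = xmin - cell; g.y0 = ymin - cell; g.z0 = zmin - cell;
  g.gx = (int)((xmax - g.x0) / cell) + 2;
  g.gy = (int)((ymax - g.y0) / cell) + 2;
  g.gz = (int)((zmax - g.z0) / cell) + 2;
  g.cells.resize((size_t)g.gx * g.gy * g.gz);
  for (size_t t = 0; t < F.size(); ++t) {
    double txmin = 1e30, tymin = 1e30, tzmin = 1e30;
    double txmax = -1e30, tymax = -1e30, tzmax = -1e30;
    for (int k = 0; k < 3; ++k) {
      const Vec3 &p = V[F[t][k]];
      txmin = std::min(txmin, p.x); txmax = std::max(txmax, p.x);
      tymin = std::min(tymin, p.y); tymax = std::max(tymax, p.y);
      tzmin = std::min(tzmin, p.z); tzmax = std::max(tzmax, p.z);
    }
    int i0 = (int)((txmin - g.x0) / cell), i1 = (int)((txmax - g.x0) / cell);
    int j0 = (int)((tymin - g.y0) / cell), j1 = (int)((tymax - g.y0) / cell);
    int k0 = (int)((tzmin - g.z0) / cell), k1 = (int)((tzmax - g.z0) / cell);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k)
          g.cells[g.cid(i, j, k)].push_back((int)t);
  }
  return g;
}

static void mesh_from_R(NumericMatrix Vin, IntegerMatrix Fin,
                        std::vector<Vec3> &V,
                        std::vector<std::array<int, 3>> &F) {
  V.resize(Vin.nrow());
  for (int i = 0; i < Vin.nrow(); ++i)
    V[i] = {Vin(i, 0), Vin(i, 1), Vin(i, 2)};
  F.resize(Fin.nrow());
  for (int i = 0; i < Fin.nrow(); ++i)
    F[i] = {Fin(i, 0) - 1, Fin(i, 1) - 1, Fin(i, 2) - 1};
}

// Exact shortest distance from each point to the mesh; returns distances,
// closest points and 1-based triangle indices.
// [[Rcpp::export]]
List point_mesh_dist_cpp(NumericMatrix P, NumericMatrix Vin,
                         IntegerMatrix Fin) {
  std::vector<Vec3> V;
  std::vector<std::array<int, 3>> F;
  mesh_from_R(Vin, Fin, V, F);
  TriGrid g = build_grid(V, F);
  int n = P.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p = {P(i, 0), P(i, 1), P(i, 2)};
    int ci = (int)((p.x - g.x0) / g.cell);
    int cj = (int)((p.y - g.y0) / g.cell);
    int ck = (int)((p.z - g.z0) / g.cell);
    ci = std::max(0, std::min(g.gx - 1, ci));
    cj = std::max(0, std::min(g.gy - 1, cj));
    ck = std::max(0, std::min(g.gz - 1, ck));
    double best = 1e30;
    Vec3 bestp = p;
    int bestt = -1;
    int maxr = std::max(g.gx, std::max(g.gy, g.gz));
    for (int r = 0; r <= maxr; ++r) {
      // shell of cells at Chebyshev radius r
      bool any = false;
      for (int di = -r; di <= r; ++di)
        for (int dj = -r; dj <= r; ++dj)
          for (int dk = -r; dk <= r; ++dk) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r)
              continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || ii >= g.gx || jj < 0 || jj >= g.gy || kk < 0 ||
                kk >= g.gz)
              continue;
            any = true;
            for (int t : g.cells[g.cid(ii, jj, kk)]) {
              Vec3 q = closest_on_tri(p, V[F[t][0]], V[F[t][1]], V[F[t][2]]);
              double d = vnorm(vsub(q, p));
              if (d < best) { best = d; bestp = q; bestt = t; }
            }
          }
      if (bestt >= 0 && best <= (r)*g.cell) break;
      if (!any && r > 0 && bestt >= 0) break;
    }
    dist[i] = best;
    closest(i, 0) = bestp.x; closest(i, 1) = bestp.y; closest(i, 2) = bestp.z;
    tri[i] = bestt + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["triangle"] = tri);
}

// ------------------------------------------------ triangle intersection QA --

// Moller 1997 interval-overlap triangle-triangle intersection test.
static bool tri_tri_overlap(const Vec3 &a0, const Vec3 &a1, const Vec3 &a2,
                            const Vec3 &b0, const Vec3 &b1, const Vec3 &b2) {
  const double EPS = 1e-12;
  Vec3 n2 = vcross(vsub(b1, b0), vsub(b2, b0));
  double d2 = -vdot(n2, b0);
  double da0 = vdot(n2, a0) + d2, da1 = vdot(n2, a1) + d2,
         da2 = vdot(n2, a2) + d2;
  if (std::fabs(da0) < EPS) da0 = 0;
  if (std::fabs(da1) < EPS) da1 = 0;
  if (std::fabs(da2) < EPS) da2 = 0;
  if ((da0 > 0 && da1 > 0 && da2 > 0) || (da0 < 0 && da1 < 0 && da2 < 0))
    return false;
  Vec3 n1 = vcross(vsub(a1, a0), vsub(a2, a0));
  double d1 = -vdot(n1, a0);
  double db0 = vdot(n1, b0) + d1, db1 = vdot(n1, b1) + d1,
         db2 = vdot(n1, b2) + d1;
  if (std::fabs(db0) < EPS) db0 = 0;
  if (std::fabs(db1) < EPS) db1 = 0;
  if (std::fabs(db2) < EPS) db2 = 0;
  if ((db0 > 0 && db1 > 0 && db2 > 0) || (db0 < 0 && db1 < 0 && db2 < 0))
    return false;
  Vec3 D = vcross(n1, n2);
  double dn = vnorm(D);
  if (dn < EPS) {
    // coplanar: conservative test via closest-point distances
    Vec3 q = closest_on_tri(a0, b0, b1, b2);
    if (vnorm(vsub(q, a0)) < EPS) return true;
    q = closest_on_tri(b0, a0, a1, a2);
    return vnorm(vsub(q, b0)) < EPS;
  }
  // interval of the triangle's crossing segment projected onto D: collect
  // the projections of all points where the triangle meets the other plane
  auto interval = [&](const Vec3 &v0, const Vec3 &v1, const Vec3 &v2,
                      double e0, double e1, double e2, double &t0,
                      double &t1) -> bool {
    const Vec3 *vv[3] = {&v0, &v1, &v2};
    double ee[3] = {e0, e1, e2};
    double pts[6];
    int np = 0;
    for (int k = 0; k < 3; ++k)
      if (ee[k] == 0) pts[np++] = vdot(D, *vv[k]);
    for (int k = 0; k < 3; ++k) {
      int l = (k + 1) % 3;
      if ((ee[k] > 0 && ee[l] < 0) || (ee[k] < 0 && ee[l] > 0)) {
        double t = ee[k] / (ee[k] - ee[l]);
        Vec3 x = {vv[k]->x + t * (vv[l]->x - vv[k]->x),
                  vv[k]->y + t * (vv[l]->y - vv[k]->y),
                  vv[k]->z + t * (vv[l]->z - vv[k]->z)};
        pts[np++] = vdot(D, x);
      }
    }
    if (np == 0) return false;
    t0 = t1 = pts[0];
    for (int k = 1; k < np; ++k) {
      t0 = std::min(t0, pts[k]);
      t1 = std::max(t1, pts[k]);
    }
    return true;
  };
  double s0, s1, t0, t1;
  if (!interval(a0, a1, a2, da0, da1, da2, s0, s1)) return false;
  if (!interval(b0, b1, b2, db0, db1, db2, t0, t1)) return false;
  return std::max(s0, t0) <= std::min(s1, t1) + EPS;
}

// Pairs of non-adjacent (no shared vertex) intersecting triangles (1-based).
// [[Rcpp::export]]
IntegerMatrix self_intersection_pairs_cpp(NumericMatrix Vin,
                                          IntegerMatrix Fin) {
  std::vector<Vec3> V;
  std::vector<std::array<int, 3>> F;
  mesh_from_R(Vin, Fin, V, F);
  TriGrid g = build_grid(V, F);
  std::set<std::pair<int, int>> seen;
  std::vector<std::pair<int, int>> hits;
  for (size_t c = 0; c < g.cells.size(); ++c) {
    auto &lst = g.cells[c];
    for (size_t i = 0; i < lst.size(); ++i)
      for (size_t j = i + 1; j < lst.size(); ++j) {
        int t1 = lst[i], t2 = lst[j];
        if (t1 > t2) std::swap(t1, t2);
        bool adj = false;
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l)
            if (F[t1][k] == F[t2][l]) adj = true;
        if (adj) continue;
        if (seen.count({t1, t2})) continue;
        seen.insert({t1, t2});
        if (tri_tri_overlap(V[F[t1][0]], V[F[t1][1]], V[F[t1][2]],
                            V[F[t2][0]], V[F[t2][1]], V[F[t2][2]]))
          hits.push_back({t1 + 1, t2 + 1});
      }
  }
  IntegerMatrix out(hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    out(k, 0) = hits[k].first;
    out(k, 1) = hits[k].second;
  }
  return out;
}

// [[Rcpp::export]]
int self_intersection_count_cpp(NumericMatrix Vin, IntegerMatrix Fin) {
  return self_intersection_pairs_cpp(Vin, Fin).nrow();
}

// -------------------------------------------------------- self-proximity ----

// For each vertex, distance/direction to the nearest triangle that contains
// no vertex within graph distance <= ring of the query vertex, capped at
// max_dist. Returns distance (Inf if none), and the unit direction from the
// closest mesh point toward the vertex (the push-apart direction).
// [[Rcpp::export]]
List vertex_proximity_cpp(NumericMatrix Vin, IntegerMatrix Fin, int ring,
                          double max_dist) {
  std::vector<Vec3> V;
  std::vector<std::array<int, 3>> F;
  mesh_from_R(Vin, Fin, V, F);
  int nv = (int)V.size();
  // vertex adjacency
  std::vector<std::set<int>> adj(nv);
  for (auto &f : F)
    for (int k = 0; k < 3; ++k) {
      adj[f[k]].insert(f[(k + 1) % 3]);
      adj[f[k]].insert(f[(k + 2) % 3]);
    }
  TriGrid g = build_grid(V, F);
  NumericVector dist(nv);
  NumericMatrix dir(nv, 3);
  std::vector<int> ringmark(nv, -1);
  for (int i = 0; i < nv; ++i) {
    // mark ring-neighbourhood of i
    std::vector<int> frontier = {i};
    ringmark[i] = i;
    std::vector<int> marked = {i};
    for (int r = 0; r < ring; ++r) {
      std::vector<int> nxt;
      for (int u : frontier)
        for (int w : adj[u])
          if (ringmark[w] != i) {
            ringmark[w] = i;
            marked.push_back(w);
            nxt.push_back(w);
          }
      frontier = nxt;
    }
    Vec3 p = V[i];
    double best = R_PosInf;
    Vec3 bestq = p;
    int ci = (int)((p.x - g.x0) / g.cell);
    int cj = (int)((p.y - g.y0) / g.cell);
    int ck = (int)((p.z - g.z0) / g.cell);
    int rad = (int)std::ceil(max_dist / g.cell) + 1;
    for (int di = -rad; di <= rad; ++di)
      for (int dj = -rad; dj <= rad; ++dj)
        for (int dk = -rad; dk <= rad; ++dk) {
          int ii = ci + di, jj = cj + dj, kk = ck + dk;
          if (ii < 0 || ii >= g.gx || jj < 0 || jj >= g.gy || kk < 0 ||
              kk >= g.gz)
            continue;
          for (int t : g.cells[g.cid(ii, jj, kk)]) {
            if (ringmark[F[t][0]] == i || ringmark[F[t][1]] == i ||
                ringmark[F[t][2]] == i)
              continue;
            Vec3 q = closest_on_tri(p, V[F[t][0]], V[F[t][1]], V[F[t][2]]);
            double d = vnorm(vsub(q, p));
            if (d < best) { best = d; bestq = q; }
          }
        }
    dist[i] = best;
    if (R_finite(best) && best > 1e-12) {
      Vec3 dvec = vsub(p, bestq);
      double n = vnorm(dvec);
      dir(i, 0) = dvec.x / n; dir(i, 1) = dvec.y / n; dir(i, 2) = dvec.z / n;
    } else {
      dir(i, 0) = dir(i, 1) = dir(i, 2) = 0;
    }
  }
  return List::create(_["distance"] = dist, _["direction"] = dir);
}

// ------------------------------------------------- spherical point location --

// Locate unit-sphere query points in a spherical triangulation; returns
// 1-based triangle index and barycentric coordinates (from the linear system
// q = a*A + b*B + c*C, normalized). Falls back to the triangle incident to
// the nearest vertex with the least-negative barycentric minimum.
// [[Rcpp::export]]
List locate_on_sphere_cpp(NumericMatrix SV, IntegerMatrix Fin,
                          NumericMatrix Q) {
  std::vector<Vec3> V;
  std::vector<std::array<int, 3>> F;
  mesh_from_R(SV, Fin, V, F);
  int nv = (int)V.size(), nq = Q.nrow();
  std::vector<std::vector<int>> vtri(nv);
  for (size_t t = 0; t < F.size(); ++t)
    for (int k = 0; k < 3; ++k) vtri[F[t][k]].push_back((int)t);
  // bucket vertices on a lat/lon grid for nearest-vertex search
  int nlat = std::max(4, (int)std::sqrt((double)nv / 4));
  int nlon = 2 * nlat;
  std::vector<std::vector<int>> buckets((size_t)nlat * nlon);
  auto bidx = [&](const Vec3 &p) {
    double lat = std::asin(std::max(-1.0, std::min(1.0, p.z)));
    double lon = std::atan2(p.y, p.x);
    int bi = (int)((lat + M_PI / 2) / M_PI * nlat);
    int bj = (int)((lon + M_PI) / (2 * M_PI) * nlon);
    bi = std::max(0, std::min(nlat - 1, bi));
    bj = std::max(0, std::min(nlon - 1, bj));
    return bi + nlat * bj;
  };
  for (int i = 0; i < nv; ++i) buckets[bidx(V[i])].push_back(i);

  auto bary = [&](int t, const Vec3 &q, double bc[3]) -> double {
    // solve q = a*A + b*B + c*C (3x3 linear system, Cramer)
    const Vec3 &A = V[F[t][0]], &B = V[F[t][1]], &C = V[F[t][2]];
    double det = A.x * (B.y * C.z - B.z * C.y) -
                 B.x * (A.y * C.z - A.z * C.y) +
                 C.x * (A.y * B.z - A.z * B.y);
    if (std::fabs(det) < 1e-14) { bc[0] = bc[1] = bc[2] = -1; return -1; }
    double a = (q.x * (B.y * C.z - B.z * C.y) -
                B.x * (q.y * C.z - q.z * C.y) +
                C.x * (q.y * B.z - q.z * B.y)) / det;
    double b = (A.x * (q.y * C.z - q.z * C.y) -
                q.x * (A.y * C.z - A.z * C.y) +
                C.x * (A.y * q.z - A.z * q.y)) / det;
    double c = (A.x * (B.y * q.z - B.z * q.y) -
                B.x * (A.y * q.z - A.z * q.y) +
                q.x * (A.y * B.z - A.z * B.y)) / det;
    double s = a + b + c;
    if (std::fabs(s) < 1e-14) { bc[0] = bc[1] = bc[2] = -1; return -1; }
    bc[0] = a / s; bc[1] = b / s; bc[2] = c / s;
    return std::min({bc[0], bc[1], bc[2]});
  };

  IntegerVector tri(nq);
  NumericMatrix barym(nq, 3);
  LogicalVector exact(nq);
  for (int qi = 0; qi < nq; ++qi) {
    Vec3 q = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    // nearest vertex via expanding bucket search
    int bestv = -1;
    double bestd = 1e30;
    double lat = std::asin(std::max(-1.0, std::min(1.0, q.z)));
    double lon = std::atan2(q.y, q.x);
    int bi = std::max(0, std::min(nlat - 1, (int)((lat + M_PI / 2) / M_PI * nlat)));
    int bj = std::max(0, std::min(nlon - 1, (int)((lon + M_PI) / (2 * M_PI) * nlon)));
    for (int r = 0; r < std::max(nlat, nlon); ++r) {
      for (int di = -r; di <= r; ++di)
        for (int dj = -r; dj <= r; ++dj) {
          if (std::max(std::abs(di), std::abs(dj)) != r) continue;
          int ii = bi + di;
          int jj = ((bj + dj) % nlon + nlon) % nlon;  // wrap longitude
          if (ii < 0 || ii >= nlat) continue;
          for (int v : buckets[ii + nlat * jj]) {
            double d = vnorm(vsub(V[v], q));
            if (d < bestd) { bestd = d; bestv = v; }
          }
        }
      if (bestv >= 0 && r >= 2) break;
    }
    // BFS over triangles from the nearest vertex
    std::set<int> visited;
    std::queue<int> tq;
    for (int t : vtri[bestv]) { tq.push(t); visited.insert(t); }
    int found = -1, bestt = -1;
    double bestmin = -1e30, bestbc[3] = {0, 0, 0};
    int expanded = 0;
    while (!tq.empty() && expanded < 400) {
      int t = tq.front(); tq.pop();
      ++expanded;
      double bc[3];
      double mn = bary(t, q, bc);
      if (mn > bestmin) {
        bestmin = mn;
        bestt = t;
        bestbc[0] = bc[0]; bestbc[1] = bc[1]; bestbc[2] = bc[2];
      }
      if (mn >= -1e-9) { found = t; break; }
      for (int k = 0; k < 3; ++k)
        for (int t2 : vtri[F[t][k]])
          if (!visited.count(t2)) { visited.insert(t2); tq.push(t2); }
    }
    if (found >= 0) {
      tri[qi] = found + 1;
      exact[qi] = true;
    } else {
      tri[qi] = bestt + 1;  // nearest-triangle fallback
      exact[qi] = false;
      // clamp negatives and renormalize
      double s = 0;
      for (int k = 0; k < 3; ++k) {
        bestbc[k] = std::max(0.0, bestbc[k]);
        s += bestbc[k];
      }
      if (s > 0)
        for (int k = 0; k < 3; ++k) bestbc[k] /= s;
    }
    if (found >= 0) {
      double bc[3];
      bary(found, q, bc);
      barym(qi, 0) = bc[0]; barym(qi, 1) = bc[1]; barym(qi, 2) = bc[2];
    } else {
      barym(qi, 0) = bestbc[0]; barym(qi, 1) = bestbc[1];
      barym(qi, 2) = bestbc[2];
    }
  }
  return List::create(_["triangle"] = tri, _["bary"] = barym,
                      _["exact"] = exact);
}
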