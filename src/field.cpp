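// Harmonic potential on the grey-matter domain (Gauss-Seidel/SOR), gradient
// streamline tracing, and trilinear volume sampling.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline bool inb(int x, int n) { return x >= 0 && x < n; }

// code: 0 outside domain, 1 interior (solve), 2 Dirichlet 0, 3 Dirichlet 1
// [[Rcpp::export]]
NumericVector laplace_sor_cpp(IntegerVector code, IntegerVector dim,
                              double tol = 1e-5, int max_iter = 5000,
                              double omega = 1.8) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  const int *c = INTEGER(code);
  NumericVector phi(ntot);
  for (size_t i = 0; i < ntot; ++i)
    phi[i] = (c[i] == 3) ? 1.0 : (c[i] == 1 ? 0.5 : 0.0);

  std::vector<size_t> interior;
  for (size_t i = 0; i < ntot; ++i)
    if (c[i] == 1) interior.push_back(i);

  static const int D[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  double resid = 0.0;
  NumericVector history;
  std::vector<double> hist;
  for (int it = 0; it < max_iter; ++it) {
    resid = 0.0;
    for (size_t k = 0; k < interior.size(); ++k) {
      size_t id = interior[k];
      int x = id % nx, y = (id / nx) % ny, z = id / ((size_t)nx * ny);
      double s = 0.0;
      int n = 0;
      for (int d = 0; d < 6; ++d) {
        int xx = x + D[d][0], yy = y + D[d][1], zz = z + D[d][2];
        if (!inb(xx, nx) || !inb(yy, ny) || !inb(zz, nz)) continue;
        size_t nid = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (c[nid] == 0) continue;  // Neumann at domain wall
        s += phi[nid];
        ++n;
      }
      if (n == 0) continue;
      double target = s / n;
      double diff = target - phi[id];
      phi[id] += omega * diff;
      double ad = std::fabs(diff);
      if (ad > resid) resid = ad;
    }
    hist.push_back(resid);
    if (resid < tol) break;
  }
  phi.attr("residual") = resid;
  phi.attr("residual_history") = NumericVector(hist.begin(), hist.end());
  return phi;
}

static double trilerp(const double *v, int nx, int ny, int nz,
                      double x, double y, double z, bool &ok) {
  // x,y,z in 0-based voxel coordinates (voxel centers at integers)
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false;
    return NA_REAL;
  }
  ok = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) --x0;
  if (y0 == ny - 1) --y0;
  if (z0 == nz - 1) --z0;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  auto at = [&](int i, int j, int k) {
    if (i >= nx) i = nx - 1;
    if (j >= ny) j = ny - 1;
    if (k >= nz) k = nz - 1;
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx;
  double c10 = at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx;
  double c01 = at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx;
  double c11 = at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  bool ok;
  for (int i = 0; i < n; ++i)
    out[i] = trilerp(REAL(vol), nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), ok);
  return out;
}

// Trace streamlines of the potential gradient from given start points (voxel
// coordinates) up the potential until phi >= 1-eps, a skeleton voxel is
// entered, or max_steps is exceeded. RK2 midpoint integration.
// [[Rcpp::export]]
List trace_streamlines_cpp(NumericVector phi, IntegerVector skel,
                           IntegerVector dim, NumericMatrix starts,
                           double step = 0.25, double eps = 0.02,
                           int max_steps = 400) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  const double *p = REAL(phi);
  const int *sk = INTEGER(skel);

  // precompute central-difference gradient fields
  std::vector<double> gx(ntot), gy(ntot), gz(ntot);
  auto id3 = [&](int x, int y, int z) {
    return (size_t)x + (size_t)nx * (y + (size_t)ny * z);
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t id = id3(x, y, z);
        int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
        int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
        int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
        gx[id] = (p[id3(xp, y, z)] - p[id3(xm, y, z)]) / (xp - xm);
        gy[id] = (p[id3(x, yp, z)] - p[id3(x, ym, z)]) / (yp - ym);
        gz[id] = (p[id3(x, y, zp)] - p[id3(x, y, zm)]) / (zp - zm);
      }

  auto grad_at = [&](double x, double y, double z, double g[3]) -> bool {
    bool ok;
    g[0] = trilerp(gx.data(), nx, ny, nz, x, y, z, ok);
    if (!ok) return false;
    g[1] = trilerp(gy.data(), nx, ny, nz, x, y, z, ok);
    g[2] = trilerp(gz.data(), nx, ny, nz, x, y, z, ok);
    double nrm = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    if (nrm < 1e-12) return false;
    g[0] /= nrm; g[1] /= nrm; g[2] /= nrm;
    return true;
  };

  int n = starts.nrow();
  NumericMatrix arrival(n, 3);
  NumericVector length(n);
  IntegerVector flag(n);  // 0 ok, 1 flagged (stalled / too long / left volume)
  for (int i = 0; i < n; ++i) {
    double x = starts(i, 0), y = starts(i, 1), z = starts(i, 2);
    double len = 0.0;
    int f = 1;
    bool ok;
    for (int s = 0; s < max_steps; ++s) {
      double ph = trilerp(p, nx, ny, nz, x, y, z, ok);
      if (!ok) { f = 1; break; }
      int xi = (int)std::lround(x), yi = (int)std::lround(y),
          zi = (int)std::lround(z);
      bool insk = inb(xi, nx) && inb(yi, ny) && inb(zi, nz) &&
                  sk[id3(xi, yi, zi)] != 0;
      if (ph >= 1.0 - eps || insk) { f = 0; break; }
      double g1[3], g2[3];
      if (!grad_at(x, y, z, g1)) { f = 1; break; }
      double mx = x + 0.5 * step * g1[0], my = y + 0.5 * step * g1[1],
             mz = z + 0.5 * step * g1[2];
      if (!grad_at(mx, my, mz, g2)) {
        g2[0] = g1[0]; g2[1] = g1[1]; g2[2] = g1[2];
      }
      x += step * g2[0]; y += step * g2[1]; z += step * g2[2];
      len += step;
    }
    arrival(i, 0) = x; arrival(i, 1) = y; arrival(i, 2) = z;
    length[i] = len;
    flag[i] = f;
  }
  return List::create(_["arrival"] = arrival, _["length"] = length,
                      _["flag"] = flag);
}
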