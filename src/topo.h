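#ifndef NEOSURF_TOPO_H
#define NEOSURF_TOPO_H

// shared digital-topology helpers (object-26 / background-6)
bool simple_point_local(const bool occ[27]);
int topo_class_from_numbers(int cs, int cb);

inline int topo_lidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

template <typename T>
void topo_fill_local(const T *obj, int nx, int ny, int nz,
                     int x, int y, int z, bool occ[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                 zz >= 0 && zz < nz &&
                 obj[xx + (size_t)nx * (yy + (size_t)ny * zz)] != 0;
        occ[topo_lidx(dx, dy, dz)] = v;
      }
}

#endif
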