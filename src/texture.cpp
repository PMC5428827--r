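#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel indexing: arrays are column-major with dims d1,d2,d3 (R layout).
static inline int idx3(int x, int y, int z, int d1, int d2) {
  return x + d1 * (y + d2 * z);
}

// Symmetric gray-level co-occurrence counts over the supplied offsets.
// levels: integer levels in 1..n_levels (values outside ignored);
// both voxels of a pair must be inside the mask. Each unordered pair is
// counted in both (i,j) and (j,i) so the count matrix is symmetric.
// [[Rcpp::export]]
IntegerMatrix cpp_glcm_counts(IntegerVector levels, LogicalVector mask,
                              IntegerVector dims, IntegerMatrix offsets,
                              int n_levels) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  IntegerMatrix counts(n_levels, n_levels);
  int n_off = offsets.nrow();
  for (int o = 0; o < n_off; ++o) {
    int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    for (int z = 0; z < d3; ++z) {
      int z2 = z + dz;
      if (z2 < 0 || z2 >= d3) continue;
      for (int y = 0; y < d2; ++y) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= d2) continue;
        for (int x = 0; x < d1; ++x) {
          int x2 = x + dx;
          if (x2 < 0 || x2 >= d1) continue;
          int a = idx3(x, y, z, d1, d2), b = idx3(x2, y2, z2, d1, d2);
          if (!mask[a] || !mask[b]) continue;
          int la = levels[a], lb = levels[b];
          if (la < 1 || la > n_levels || lb < 1 || lb > n_levels) continue;
          counts(la - 1, lb - 1) += 1;
          counts(lb - 1, la - 1) += 1;
        }
      }
    }
  }
  return counts;
}

// Neighborhood gray-tone difference accumulation over the 26-connected
// 3D neighborhood restricted to the mask. Voxels with no in-mask
// neighbor are excluded. Returns an n_levels x 2 matrix with columns
// (n_i, s_i) where s_i sums |level - mean(neighbor levels)|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, LogicalVector mask,
                        IntegerVector dims, int n_levels) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(n_levels, 2);
  for (int z = 0; z < d3; ++z) {
    for (int y = 0; y < d2; ++y) {
      for (int x = 0; x < d1; ++x) {
        int a = idx3(x, y, z, d1, d2);
        if (!mask[a]) continue;
        int la = levels[a];
        if (la < 1 || la > n_levels) continue;
        double nb_sum = 0.0;
        int nb_n = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int z2 = z + dz;
          if (z2 < 0 || z2 >= d3) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int y2 = y + dy;
            if (y2 < 0 || y2 >= d2) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx;
              if (x2 < 0 || x2 >= d1) continue;
              int b = idx3(x2, y2, z2, d1, d2);
              if (!mask[b]) continue;
              int lb = levels[b];
              if (lb < 1 || lb > n_levels) continue;
              nb_sum += lb;
              nb_n += 1;
            }
          }
        }
        if (nb_n == 0) continue;
        out(la - 1, 0) += 1.0;
        out(la - 1, 1) += std::fabs((double)la - nb_sum / nb_n);
      }
    }
  }
  return out;
}

// Gray-level run-length counts: maximal runs of constant level along
// each direction, broken at the mask boundary. A voxel starts a run if
// its predecessor along -d is outside the grid/mask or has a different
// level. Returns n_levels x max_len counts.
// [[Rcpp::export]]
IntegerMatrix cpp_rlm_counts(IntegerVector levels, LogicalVector mask,
                             IntegerVector dims, IntegerMatrix directions,
                             int n_levels) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int max_len = d1 + d2 + d3;  // safe upper bound on any run length
  IntegerMatrix counts(n_levels, max_len);
  int n_dir = directions.nrow();
  for (int o = 0; o < n_dir; ++o) {
    int dx = directions(o, 0), dy = directions(o, 1), dz = directions(o, 2);
    for (int z = 0; z < d3; ++z) {
      for (int y = 0; y < d2; ++y) {
        for (int x = 0; x < d1; ++x) {
          int a = idx3(x, y, z, d1, d2);
          if (!mask[a]) continue;
          int la = levels[a];
          if (la < 1 || la > n_levels) continue;
          // run start check: predecessor invalid or different level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < d1 && yp >= 0 && yp < d2 && zp >= 0 && zp < d3) {
            int p = idx3(xp, yp, zp, d1, d2);
            if (mask[p] && levels[p] == la) continue;  // mid-run
          }
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < d1 && yn >= 0 && yn < d2 && zn >= 0 &&
                 zn < d3) {
            int b = idx3(xn, yn, zn, d1, d2);
            if (!mask[b] || levels[b] != la) break;
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          if (len > max_len) len = max_len;
          counts(la - 1, len - 1) += 1;
        }
      }
    }
  }
  return counts;
}

// ---- Isosurface area/volume via marching tetrahedra ------------------
// field: smooth scalar field (column-major), iso: level; spacing in mm.
// Each cell is split into 6 tetrahedra sharing the main diagonal; the
// iso-level crossing within each tetrahedron is triangulated with
// linearly interpolated edge vertices. Triangles are oriented outward
// (checked against an interior vertex), so the divergence theorem gives
// the enclosed volume. The field must be < iso on the array boundary so
// the surface is closed.
struct P3 { double x, y, z; };

static inline P3 lerp_edge(const P3 &a, const P3 &b, double fa, double fb,
                           double iso) {
  double t = (iso - fa) / (fb - fa);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline void add_tri(const P3 &p0, const P3 &p1, const P3 &p2,
                           const P3 &inside, double &area, double &vol) {
  double ux = p1.x - p0.x, uy = p1.y - p0.y, uz = p1.z - p0.z;
  double vx = p2.x - p0.x, vy = p2.y - p0.y, vz = p2.z - p0.z;
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double cx = (p0.x + p1.x + p2.x) / 3.0 - inside.x;
  double cy = (p0.y + p1.y + p2.y) / 3.0 - inside.y;
  double cz = (p0.z + p1.z + p2.z) / 3.0 - inside.z;
  double s = 1.0;
  if (nx * cx + ny * cy + nz * cz < 0) { nx = -nx; ny = -ny; nz = -nz; s = -1.0; }
  area += 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
  // signed volume contribution of oriented triangle w.r.t. origin
  double det = p0.x * (p1.y * p2.z - p1.z * p2.y) -
               p0.y * (p1.x * p2.z - p1.z * p2.x) +
               p0.z * (p1.x * p2.y - p1.y * p2.x);
  vol += s * det / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, IntegerVector dims,
                                   NumericVector spacing, double iso) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // 6-tetra decomposition of the unit cube around diagonal c0-c7,
  // corners numbered x + 2y + 4z
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  static const int cdx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  static const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  double area = 0.0, vol = 0.0;
  for (int z = 0; z + 1 < d3; ++z) {
    for (int y = 0; y + 1 < d2; ++y) {
      for (int x = 0; x + 1 < d1; ++x) {
        double f[8];
        P3 c[8];
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k) {
          int xx = x + cdx[k], yy = y + cdy[k], zz = z + cdz[k];
          f[k] = field[idx3(xx, yy, zz, d1, d2)];
          c[k].x = xx * sx; c[k].y = yy * sy; c[k].z = zz * sz;
          if (f[k] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *v = tets[t];
          int in[4], nin = 0, nout = 0, ins[4], outs[4];
          for (int k = 0; k < 4; ++k) {
            in[k] = f[v[k]] >= iso;
            if (in[k]) ins[nin++] = v[k]; else outs[nout++] = v[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // single triangle separating the odd vertex
            int a = (nin == 1) ? ins[0] : outs[0];
            int others[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (v[k] != a) others[m++] = v[k];
            P3 p0 = lerp_edge(c[a], c[others[0]], f[a], f[others[0]], iso);
            P3 p1 = lerp_edge(c[a], c[others[1]], f[a], f[others[1]], iso);
            P3 p2 = lerp_edge(c[a], c[others[2]], f[a], f[others[2]], iso);
            const P3 &ref = (nin == 1) ? c[a] : c[ins[0]];
            add_tri(p0, p1, p2, ref, area, vol);
          } else {
            // quad: edges (i0,o0),(i0,o1),(i1,o1),(i1,o0) in cyclic order
            int i0 = ins[0], i1 = ins[1], o0 = outs[0], o1 = outs[1];
            P3 q0 = lerp_edge(c[i0], c[o0], f[i0], f[o0], iso);
            P3 q1 = lerp_edge(c[i0], c[o1], f[i0], f[o1], iso);
            P3 q2 = lerp_edge(c[i1], c[o1], f[i1], f[o1], iso);
            P3 q3 = lerp_edge(c[i1], c[o0], f[i1], f[o0], iso);
            P3 ref;
            ref.x = 0.5 * (c[i0].x + c[i1].x);
            ref.y = 0.5 * (c[i0].y + c[i1].y);
            ref.z = 0.5 * (c[i0].z + c[i1].z);
            add_tri(q0, q1, q2, ref, area, vol);
            add_tri(q0, q2, q3, ref, area, vol);
          }
        }
      }
    }
  }
  return NumericVector::create(area, std::fabs(vol));
}
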