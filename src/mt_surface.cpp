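#include <Rcpp.h>
#include <unordered_map>
#include "geomutil.h"
using namespace Rcpp;
using hm::Vec3;

// Iso-surface extraction by marching tetrahedra on a body-centered (BCC)
// decomposition of the voxel grid.  Grid corners carry the sampled field;
// cell centers carry the 8-corner mean (the trilinear value at the center).
// Each pair of face-adjacent cells contributes 4 tetrahedra spanning the two
// centers and an edge of the shared face; boundary faces contribute pyramid
// halves so the whole box is tiled conformally.  Cut vertices are welded by
// lattice-edge key, which makes the output watertight by construction.

namespace {

struct MTState {
  std::vector<double> vx, vy, vz;        // output vertices (mm)
  std::vector<int> tri;                  // output faces, flattened 0-based
  std::unordered_map<uint64_t, int> weld;
  const double* f;                       // corner field
  const std::vector<double>* fc;         // center field
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
  double iso;
  size_t ncorner;

  inline bool inside(double v) const { return v > iso; }

  inline Vec3 pos(uint64_t id) const {
    if (id < ncorner) {
      int i = id % nx, j = (id / nx) % ny, k = id / ((size_t)nx * ny);
      return Vec3(ox + i * sx, oy + j * sy, oz + k * sz);
    }
    size_t c = id - ncorner;
    int cx = nx - 1, cy = ny - 1;
    int i = c % cx, j = (c / cx) % cy, k = c / ((size_t)cx * cy);
    return Vec3(ox + (i + 0.5) * sx, oy + (j + 0.5) * sy, oz + (k + 0.5) * sz);
  }

  inline double val(uint64_t id) const {
    if (id < ncorner) return f[id];
    return (*fc)[id - ncorner];
  }

  int cutpoint(uint64_t a, uint64_t b) {
    uint64_t key = hm::edge_key(a, b);
    auto it = weld.find(key);
    if (it != weld.end()) return it->second;
    double fa = val(a), fb = val(b);
    double t = (iso - fa) / (fb - fa);
    // keep cut points away from lattice vertices: bounds the smallest
    // facet size (and so the worst facet shape) at a sub-voxel positional
    // cost that is symmetric and volume-neutral on average
    const double TCLAMP = 0.12;
    if (t < TCLAMP) t = TCLAMP;
    if (t > 1.0 - TCLAMP) t = 1.0 - TCLAMP;
    Vec3 pa = pos(a), pb = pos(b);
    Vec3 p = pa + (pb - pa) * t;
    int idx = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    weld.emplace(key, idx);
    return idx;
  }

  void emit(int a, int b, int c, const Vec3& want_dir) {
    // orient so the normal has positive dot with want_dir (inside -> outside)
    Vec3 pa(vx[a], vy[a], vz[a]), pb(vx[b], vy[b], vz[b]), pc(vx[c], vy[c], vz[c]);
    Vec3 n = hm::cross(pb - pa, pc - pa);
    if (hm::dot(n, want_dir) < 0.0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }

  void do_tet(uint64_t g0, uint64_t g1, uint64_t g2, uint64_t g3) {
    uint64_t g[4] = {g0, g1, g2, g3};
    double v[4];
    bool in[4];
    int nin = 0;
    for (int i = 0; i < 4; ++i) {
      v[i] = val(g[i]);
      in[i] = inside(v[i]);
      nin += in[i];
    }
    if (nin == 0 || nin == 4) return;
    if (nin == 1 || nin == 3) {
      bool lone_in = (nin == 1);
      int lone = -1;
      for (int i = 0; i < 4; ++i)
        if (in[i] == lone_in) lone = i;
      int o[3], m = 0;
      for (int i = 0; i < 4; ++i)
        if (i != lone) o[m++] = i;
      int p0 = cutpoint(g[lone], g[o[0]]);
      int p1 = cutpoint(g[lone], g[o[1]]);
      int p2 = cutpoint(g[lone], g[o[2]]);
      Vec3 apex = pos(g[lone]);
      Vec3 cen((vx[p0] + vx[p1] + vx[p2]) / 3.0, (vy[p0] + vy[p1] + vy[p2]) / 3.0,
               (vz[p0] + vz[p1] + vz[p2]) / 3.0);
      Vec3 dir = lone_in ? (cen - apex) : (apex - cen);
      emit(p0, p1, p2, dir);
    } else {
      // two in (A,B), two out (C,D): quad pAC, pAD, pBD, pBC
      int A = -1, B = -1, C = -1, D = -1;
      for (int i = 0; i < 4; ++i) {
        if (in[i]) { if (A < 0) A = i; else B = i; }
        else { if (C < 0) C = i; else D = i; }
      }
      int pac = cutpoint(g[A], g[C]);
      int pad = cutpoint(g[A], g[D]);
      int pbd = cutpoint(g[B], g[D]);
      int pbc = cutpoint(g[B], g[C]);
      Vec3 cin = (pos(g[A]) + pos(g[B])) * 0.5;
      Vec3 cout = (pos(g[C]) + pos(g[D])) * 0.5;
      Vec3 dir = cout - cin;
      int q[4] = {pac, pad, pbd, pbc};
      // fan from the smallest vertex index for determinism
      int m = 0;
      for (int i = 1; i < 4; ++i)
        if (q[i] < q[m]) m = i;
      emit(q[m], q[(m + 1) % 4], q[(m + 2) % 4], dir);
      emit(q[m], q[(m + 2) % 4], q[(m + 3) % 4], dir);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_isosurface(NumericVector vol, IntegerVector dims, NumericVector origin,
                    NumericVector spacing, double iso) {
  MTState st;
  st.nx = dims[0]; st.ny = dims[1]; st.nz = dims[2];
  st.ox = origin[0]; st.oy = origin[1]; st.oz = origin[2];
  st.sx = spacing[0]; st.sy = spacing[1]; st.sz = spacing[2];
  st.iso = iso;
  st.f = vol.begin();
  st.ncorner = (size_t)st.nx * st.ny * st.nz;

  int cx = st.nx - 1, cy = st.ny - 1, cz = st.nz - 1;
  if (cx < 1 || cy < 1 || cz < 1)
    stop("volume must have at least 2 voxels per dimension");
  std::vector<double> fc((size_t)cx * cy * cz);
  for (int k = 0; k < cz; ++k)
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        double s = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              s += vol[(size_t)(i + di) + (size_t)st.nx * ((j + dj) + (size_t)st.ny * (k + dk))];
        fc[(size_t)i + (size_t)cx * (j + (size_t)cy * k)] = s / 8.0;
      }
  st.fc = &fc;

  auto corner_id = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)st.nx * ((uint64_t)j + (uint64_t)st.ny * k);
  };
  auto center_id = [&](int i, int j, int k) -> uint64_t {
    return st.ncorner + (uint64_t)i + (uint64_t)cx * ((uint64_t)j + (uint64_t)cy * k);
  };

  // interior faces between cell (i,j,k) and its +axis neighbor
  for (int k = 0; k < cz; ++k)
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        uint64_t c1 = center_id(i, j, k);
        for (int axis = 0; axis < 3; ++axis) {
          int ni = i + (axis == 0), nj = j + (axis == 1), nk = k + (axis == 2);
          // shared face corner coordinates (the +axis face of cell i,j,k)
          int fi = i + (axis == 0), fj = j + (axis == 1), fk = k + (axis == 2);
          uint64_t q[4];
          if (axis == 0) {
            q[0] = corner_id(fi, j, k);     q[1] = corner_id(fi, j + 1, k);
            q[2] = corner_id(fi, j + 1, k + 1); q[3] = corner_id(fi, j, k + 1);
          } else if (axis == 1) {
            q[0] = corner_id(i, fj, k);     q[1] = corner_id(i + 1, fj, k);
            q[2] = corner_id(i + 1, fj, k + 1); q[3] = corner_id(i, fj, k + 1);
          } else {
            q[0] = corner_id(i, j, fk);     q[1] = corner_id(i + 1, j, fk);
            q[2] = corner_id(i + 1, j + 1, fk); q[3] = corner_id(i, j + 1, fk);
          }
          bool has_nb = (axis == 0 ? ni < cx : (axis == 1 ? nj < cy : nk < cz));
          if (has_nb) {
            uint64_t c2 = center_id(ni, nj, nk);
            for (int e = 0; e < 4; ++e)
              st.do_tet(c1, c2, q[e], q[(e + 1) % 4]);
          } else {
            // boundary pyramid: split quad by diagonal at min corner id
            int m = 0;
            for (int e = 1; e < 4; ++e)
              if (q[e] < q[m]) m = e;
            st.do_tet(c1, q[m], q[(m + 1) % 4], q[(m + 2) % 4]);
            st.do_tet(c1, q[m], q[(m + 2) % 4], q[(m + 3) % 4]);
          }
        }
        // -axis boundary faces (only for cells at the low border)
        for (int axis = 0; axis < 3; ++axis) {
          bool low = (axis == 0 ? i == 0 : (axis == 1 ? j == 0 : k == 0));
          if (!low) continue;
          uint64_t q[4];
          if (axis == 0) {
            q[0] = corner_id(0, j, k);     q[1] = corner_id(0, j + 1, k);
            q[2] = corner_id(0, j + 1, k + 1); q[3] = corner_id(0, j, k + 1);
          } else if (axis == 1) {
            q[0] = corner_id(i, 0, k);     q[1] = corner_id(i + 1, 0, k);
            q[2] = corner_id(i + 1, 0, k + 1); q[3] = corner_id(i, 0, k + 1);
          } else {
            q[0] = corner_id(i, j, 0);     q[1] = corner_id(i + 1, j, 0);
            q[2] = corner_id(i + 1, j + 1, 0); q[3] = corner_id(i, j + 1, 0);
          }
          int m = 0;
          for (int e = 1; e < 4; ++e)
            if (q[e] < q[m]) m = e;
          st.do_tet(c1, q[m], q[(m + 1) % 4], q[(m + 2) % 4]);
          st.do_tet(c1, q[m], q[(m + 2) % 4], q[(m + 3) % 4]);
        }
      }

  int nv = (int)st.vx.size(), nf = (int)(st.tri.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.tri[3 * i]; F(i, 1) = st.tri[3 * i + 1]; F(i, 2) = st.tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
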