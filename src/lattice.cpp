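#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <climits>
#include "geomutil.h"
using namespace Rcpp;
using hm::Vec3;

// Background-lattice tetrahedralizer.  A body-centered-cubic (BCC) lattice of
// near-regular tetrahedra tiles the bounding box; each closed input surface is
// then imprinted by (1) snapping lattice vertices that lie within a tolerance
// of the surface onto their closest surface point and (2) splitting the
// remaining crossed tetrahedra along the linearly interpolated zero set of the
// vertex signed distances.  Because every element ends up strictly on one side
// of each surface, region membership is unambiguous and the element volumes
// partition the meshed domain exactly.

// ---------------------------------------------------------------------------
// BCC lattice over a box: corners + cell centers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bcc_mesh(NumericVector lo, IntegerVector ncell, double h) {
  int cx = ncell[0], cy = ncell[1], cz = ncell[2];
  int nx = cx + 1, ny = cy + 1, nz = cz + 1;
  size_t ncorner = (size_t)nx * ny * nz;
  size_t ncenter = (size_t)cx * cy * cz;
  size_t nv = ncorner + ncenter;
  NumericMatrix V((int)nv, 3);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        V(id, 0) = lo[0] + i * h;
        V(id, 1) = lo[1] + j * h;
        V(id, 2) = lo[2] + k * h;
      }
  for (int k = 0; k < cz; ++k)
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        size_t id = ncorner + (size_t)i + (size_t)cx * (j + (size_t)cy * k);
        V(id, 0) = lo[0] + (i + 0.5) * h;
        V(id, 1) = lo[1] + (j + 0.5) * h;
        V(id, 2) = lo[2] + (k + 0.5) * h;
      }
  auto corner_id = [&](int i, int j, int k) -> int {
    return (int)((size_t)i + (size_t)nx * (j + (size_t)ny * k));
  };
  auto center_id = [&](int i, int j, int k) -> int {
    return (int)(ncorner + (size_t)i + (size_t)cx * (j + (size_t)cy * k));
  };
  std::vector<int> T;
  T.reserve(12 * ncenter * 4);
  auto push_tet = [&](int a, int b, int c, int d) {
    Vec3 pa(V(a, 0), V(a, 1), V(a, 2)), pb(V(b, 0), V(b, 1), V(b, 2)),
        pc(V(c, 0), V(c, 1), V(c, 2)), pd(V(d, 0), V(d, 1), V(d, 2));
    if (hm::tet_signed_volume(pa, pb, pc, pd) < 0) std::swap(c, d);
    T.push_back(a); T.push_back(b); T.push_back(c); T.push_back(d);
  };
  for (int k = 0; k < cz; ++k)
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        int c1 = center_id(i, j, k);
        for (int axis = 0; axis < 3; ++axis) {
          int ni = i + (axis == 0), nj = j + (axis == 1), nk = k + (axis == 2);
          int fi = i + (axis == 0), fj = j + (axis == 1), fk = k + (axis == 2);
          int q[4];
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
            int c2 = center_id(ni, nj, nk);
            for (int e = 0; e < 4; ++e)
              push_tet(c1, c2, q[e], q[(e + 1) % 4]);
          } else {
            int m = 0;
            for (int e = 1; e < 4; ++e)
              if (q[e] < q[m]) m = e;
            push_tet(c1, q[m], q[(m + 1) % 4], q[(m + 2) % 4]);
            push_tet(c1, q[m], q[(m + 2) % 4], q[(m + 3) % 4]);
          }
        }
        for (int axis = 0; axis < 3; ++axis) {
          bool low = (axis == 0 ? i == 0 : (axis == 1 ? j == 0 : k == 0));
          if (!low) continue;
          int q[4];
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
          push_tet(c1, q[m], q[(m + 1) % 4], q[(m + 2) % 4]);
          push_tet(c1, q[m], q[(m + 2) % 4], q[(m + 3) % 4]);
        }
      }
  int nt = (int)(T.size() / 4);
  IntegerMatrix Tm(nt, 4);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c)
      Tm(t, c) = T[4 * t + c];
  return List::create(_["vertices"] = V, _["tets"] = Tm);
}

// ---------------------------------------------------------------------------
// vertex snapping
// ---------------------------------------------------------------------------

// Move eligible vertices with 0 < |d| <= threshold onto their closest surface
// point, unless doing so degenerates an incident tetrahedron.  d entries of
// snapped vertices become exactly 0.
// [[Rcpp::export]]
List cpp_snap_vertices(NumericMatrix V, IntegerMatrix T, NumericVector d,
                       NumericMatrix closest, double threshold,
                       LogicalVector eligible) {
  int nv = V.nrow(), nt = T.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  // incidence
  std::vector<int> cnt(nv, 0);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c) cnt[T(t, c)]++;
  std::vector<int> start(nv + 1, 0);
  for (int i = 0; i < nv; ++i) start[i + 1] = start[i] + cnt[i];
  std::vector<int> inc(start[nv]);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c) inc[fill[T(t, c)]++] = t;
  NumericVector d2 = clone(d);
  LogicalVector snapped(nv);
  int nsnap = 0;
  for (int i = 0; i < nv; ++i) {
    if (!eligible[i]) continue;
    double ad = std::fabs(d2[i]);
    if (ad == 0.0 || ad > threshold) continue;
    if (NumericVector::is_na(closest(i, 0))) continue;
    Vec3 cand(closest(i, 0), closest(i, 1), closest(i, 2));
    bool ok = true;
    for (int s = start[i]; s < start[i + 1] && ok; ++s) {
      int t = inc[s];
      Vec3 q[4];
      for (int c = 0; c < 4; ++c) q[c] = P[T(t, c)];
      double vol_old = hm::tet_signed_volume(q[0], q[1], q[2], q[3]);
      for (int c = 0; c < 4; ++c)
        if (T(t, c) == i) q[c] = cand;
      double vol_new = hm::tet_signed_volume(q[0], q[1], q[2], q[3]);
      if (!(vol_new > 0.02 * vol_old)) ok = false;
    }
    if (ok) {
      P[i] = cand;
      d2[i] = 0.0;
      snapped[i] = true;
      ++nsnap;
    }
  }
  NumericMatrix V2(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  return List::create(_["vertices"] = V2, _["distance"] = d2,
                      _["snapped"] = snapped, _["n_snapped"] = nsnap);
}

// Stuffing-style snap: a vertex is snapped onto the surface when the cut
// point on one of its incident edges falls within fraction `alpha` of it,
// i.e. when cutting would create an edge shorter than alpha times the local
// edge length.  Vertices are processed by increasing |d| over two passes so
// that resolved crossings release their partners.
// [[Rcpp::export]]
List cpp_snap_for_cut(NumericMatrix V, IntegerMatrix T, NumericVector d,
                      NumericMatrix closest, double alpha, double tol) {
  int nv = V.nrow(), nt = T.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  std::vector<int> cnt(nv, 0);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c) cnt[T(t, c)]++;
  std::vector<int> start(nv + 1, 0);
  for (int i = 0; i < nv; ++i) start[i + 1] = start[i] + cnt[i];
  std::vector<int> inc(start[nv]);
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int t = 0; t < nt; ++t)
      for (int c = 0; c < 4; ++c) inc[fill[T(t, c)]++] = t;
  }
  NumericVector d2 = clone(d);
  LogicalVector snapped(nv);
  auto val = [&](int i) {
    return std::fabs(d2[i]) <= tol ? 0.0 : (double)d2[i];
  };
  int nsnap = 0;
  for (int pass = 0; pass < 2; ++pass) {
    // mark vertices with a too-close incident cut
    std::vector<char> mark(nv, 0);
    std::unordered_map<uint64_t, char> seen;
    for (int t = 0; t < nt; ++t)
      for (int a = 0; a < 4; ++a)
        for (int b = a + 1; b < 4; ++b) {
          int va = T(t, a), vb = T(t, b);
          uint64_t key = hm::edge_key((uint64_t)va, (uint64_t)vb);
          if (!seen.emplace(key, 1).second) continue;
          double da = val(va), db = val(vb);
          if (!((da < 0 && db > 0) || (da > 0 && db < 0))) continue;
          double tt = da / (da - db);
          if (tt < alpha) mark[va] = 1;
          if (tt > 1.0 - alpha) mark[vb] = 1;
        }
    std::vector<int> order;
    for (int i = 0; i < nv; ++i)
      if (mark[i] && !snapped[i] && !NumericVector::is_na(closest(i, 0)))
        order.push_back(i);
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      double fa = std::fabs(d2[a]), fb = std::fabs(d2[b]);
      return fa != fb ? fa < fb : a < b;
    });
    int moved = 0;
    for (int i : order) {
      if (val(i) == 0.0) { d2[i] = 0.0; snapped[i] = true; continue; }
      Vec3 cand(closest(i, 0), closest(i, 1), closest(i, 2));
      bool ok = true;
      for (int s = start[i]; s < start[i + 1] && ok; ++s) {
        int t = inc[s];
        Vec3 q[4];
        for (int c = 0; c < 4; ++c) q[c] = P[T(t, c)];
        double vol_old = hm::tet_signed_volume(q[0], q[1], q[2], q[3]);
        for (int c = 0; c < 4; ++c)
          if (T(t, c) == i) q[c] = cand;
        double vol_new = hm::tet_signed_volume(q[0], q[1], q[2], q[3]);
        if (!(vol_new > 0.02 * vol_old)) ok = false;
      }
      if (ok) {
        P[i] = cand;
        d2[i] = 0.0;
        snapped[i] = true;
        ++nsnap;
        ++moved;
      }
    }
    if (moved == 0) break;
  }
  NumericMatrix V2(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  return List::create(_["vertices"] = V2, _["distance"] = d2,
                      _["snapped"] = snapped, _["n_snapped"] = nsnap);
}

// ---------------------------------------------------------------------------
// cut a tet mesh by a per-vertex linear field (negative = inside)
// ---------------------------------------------------------------------------

namespace {

struct CutCtx {
  std::vector<Vec3> P;                       // positions incl. new cut points
  std::unordered_map<uint64_t, int> weld;    // edge key -> cut vertex id
  const double* d;
  int nv_in;
  double tol;

  double val(int id) const {
    if (id >= nv_in) return 0.0;  // cut vertices sit on the surface
    double v = d[id];
    return std::fabs(v) <= tol ? 0.0 : v;
  }
  bool on_plane(int id) const { return val(id) == 0.0; }

  int cutpoint(int a, int b) {
    uint64_t key = hm::edge_key((uint64_t)a, (uint64_t)b);
    auto it = weld.find(key);
    if (it != weld.end()) return it->second;
    double da = val(a), db = val(b);
    double t = da / (da - db);
    Vec3 p = P[a] + (P[b] - P[a]) * t;
    int id = (int)P.size();
    P.push_back(p);
    weld.emplace(key, id);
    return id;
  }
};

// clip an (outward-wound) triangle by the field; appends polygons
void clip_face(CutCtx& cx, const int f[3], std::vector<int>& neg,
               std::vector<int>& pos) {
  neg.clear();
  pos.clear();
  for (int e = 0; e < 3; ++e) {
    int p = f[e], q = f[(e + 1) % 3];
    double dp = cx.val(p), dq = cx.val(q);
    if (dp < 0) neg.push_back(p);
    else if (dp > 0) pos.push_back(p);
    else { neg.push_back(p); pos.push_back(p); }
    if ((dp < 0 && dq > 0) || (dp > 0 && dq < 0)) {
      int c = cx.cutpoint(p, q);
      neg.push_back(c);
      pos.push_back(c);
    }
  }
}

// triangulate polygon (winding preserved); quad split by min-id diagonal,
// larger polygons fanned from min id (shared faces are at most quads)
void tri_poly(const std::vector<int>& poly, std::vector<std::array<int, 3>>& out) {
  int n = (int)poly.size();
  if (n < 3) return;
  int m = 0;
  for (int i = 1; i < n; ++i)
    if (poly[i] < poly[m]) m = i;
  for (int i = 1; i + 1 < n; ++i)
    out.push_back({poly[m], poly[(m + i) % n], poly[(m + i + 1) % n]});
}

}  // namespace

// Cut: returns new vertices, new tets, per-tet side (1 = inside/negative) and
// per-tet parent (1-based row in input T).
// [[Rcpp::export]]
List cpp_cut_by_field(NumericMatrix V, IntegerMatrix T, NumericVector d,
                      double tol, double vol_floor) {
  int nv = V.nrow(), nt = T.nrow();
  CutCtx cx;
  cx.P.resize(nv);
  for (int i = 0; i < nv; ++i) cx.P[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  cx.d = d.begin();
  cx.nv_in = nv;
  cx.tol = tol;

  std::vector<int> outT;
  std::vector<int> side, parent;
  int n_dropped = 0;
  outT.reserve((size_t)nt * 4);

  const int FACES[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};

  std::vector<int> negp, posp;
  std::vector<std::array<int, 3>> neg_tris, pos_tris, cs_tris;
  std::vector<std::pair<int, int>> plane_edges;

  for (int t = 0; t < nt; ++t) {
    int g[4] = {T(t, 0), T(t, 1), T(t, 2), T(t, 3)};
    double dv[4];
    bool has_in = false, has_out = false;
    for (int c = 0; c < 4; ++c) {
      dv[c] = cx.val(g[c]);
      has_in = has_in || dv[c] < 0;
      has_out = has_out || dv[c] > 0;
    }
    if (!has_in || !has_out) {
      outT.push_back(g[0]); outT.push_back(g[1]);
      outT.push_back(g[2]); outT.push_back(g[3]);
      side.push_back(has_in ? 1 : 0);
      parent.push_back(t + 1);
      continue;
    }
    // clip all 4 outward faces
    neg_tris.clear(); pos_tris.clear(); cs_tris.clear();
    plane_edges.clear();
    for (int fidx = 0; fidx < 4; ++fidx) {
      int f[3] = {g[FACES[fidx][0]], g[FACES[fidx][1]], g[FACES[fidx][2]]};
      clip_face(cx, f, negp, posp);
      // record directed plane edges of the neg polygon (consecutive on-plane
      // vertices); the cross-section must traverse them reversed.  Degenerate
      // (<3 vertex) polygons are zero-area slivers, not real faces: skip.
      int n = (int)negp.size() >= 3 ? (int)negp.size() : 0;
      for (int e = 0; e < n; ++e) {
        int p = negp[e], q = negp[(e + 1) % n];
        bool pp = (p >= cx.nv_in) || cx.on_plane(p);
        bool qq = (q >= cx.nv_in) || cx.on_plane(q);
        if (pp && qq) plane_edges.emplace_back(q, p);  // reversed
      }
      tri_poly(negp, neg_tris);
      tri_poly(posp, pos_tris);
    }
    // assemble cross-section polygon by chaining reversed plane edges
    std::vector<int> cs;
    if (!plane_edges.empty()) {
      std::unordered_map<int, int> nxt;
      for (auto& pe : plane_edges) nxt[pe.first] = pe.second;
      int start = plane_edges[0].first, cur = start;
      bool closed = false;
      for (size_t step = 0; step <= plane_edges.size(); ++step) {
        cs.push_back(cur);
        auto it = nxt.find(cur);
        if (it == nxt.end()) break;
        cur = it->second;
        if (cur == start) { closed = true; break; }
      }
      if (!closed || cs.size() < 3) cs.clear();
    }
    if (cs.size() >= 3) {
      tri_poly(cs, cs_tris);
      for (auto& tr : cs_tris) {
        neg_tris.push_back(tr);
        pos_tris.push_back({tr[0], tr[2], tr[1]});
      }
    }
    // cone each side from its minimum-id vertex
    for (int sidefl = 0; sidefl < 2; ++sidefl) {
      auto& tris = sidefl == 0 ? neg_tris : pos_tris;
      int apex = INT_MAX;
      for (auto& tr : tris)
        for (int c = 0; c < 3; ++c) apex = std::min(apex, tr[c]);
      for (auto& tr : tris) {
        if (tr[0] == apex || tr[1] == apex || tr[2] == apex) continue;
        double vol = hm::tet_signed_volume(cx.P[apex], cx.P[tr[0]], cx.P[tr[1]],
                                           cx.P[tr[2]]);
        if (vol <= vol_floor) {
          if (vol < -vol_floor) ++n_dropped;
          continue;
        }
        outT.push_back(apex); outT.push_back(tr[0]);
        outT.push_back(tr[1]); outT.push_back(tr[2]);
        side.push_back(sidefl == 0 ? 1 : 0);
        parent.push_back(t + 1);
      }
    }
  }

  int nv2 = (int)cx.P.size(), nt2 = (int)(side.size());
  NumericMatrix V2(nv2, 3);
  for (int i = 0; i < nv2; ++i) {
    V2(i, 0) = cx.P[i].x; V2(i, 1) = cx.P[i].y; V2(i, 2) = cx.P[i].z;
  }
  IntegerMatrix T2(nt2, 4);
  for (int t = 0; t < nt2; ++t)
    for (int c = 0; c < 4; ++c)
      T2(t, c) = outT[4 * (size_t)t + c];
  return List::create(_["vertices"] = V2, _["tets"] = T2,
                      _["side"] = IntegerVector(side.begin(), side.end()),
                      _["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["n_dropped"] = n_dropped);
}

// ---------------------------------------------------------------------------
// element metrics
// ---------------------------------------------------------------------------

namespace {

void tet_metrics_one(const Vec3& a, const Vec3& b, const Vec3& c, const Vec3& e,
                     double& vol, double& re, double& jl) {
  vol = hm::tet_signed_volume(a, b, c, e);
  double av = std::fabs(vol);
  Vec3 pts[4] = {a, b, c, e};
  double sum2 = 0, lmin2 = 1e300;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      double l2 = hm::dist2(pts[i], pts[j]);
      sum2 += l2;
      lmin2 = std::min(lmin2, l2);
    }
  jl = sum2 > 0 ? 12.0 * std::pow(3.0 * av, 2.0 / 3.0) / sum2 : 0.0;
  // circumcenter: solve 2 (p_i - a) . x = |p_i - a|^2, x = c - a
  Vec3 u = b - a, v = c - a, w = e - a;
  double m[3][3] = {{u.x, u.y, u.z}, {v.x, v.y, v.z}, {w.x, w.y, w.z}};
  double rhs[3] = {hm::dot(u, u) / 2, hm::dot(v, v) / 2, hm::dot(w, w) / 2};
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
               m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
               m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-300) {
    re = R_PosInf;
    return;
  }
  double x = (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
              m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
              m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2])) / det;
  double y = (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
              rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
              m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])) / det;
  double z = (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
              m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
              rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0])) / det;
  double R = std::sqrt(x * x + y * y + z * z);
  re = R / std::sqrt(lmin2);
}

}  // namespace

// [[Rcpp::export]]
List cpp_tet_metrics(NumericMatrix V, IntegerMatrix T) {
  int nt = T.nrow();
  NumericVector vol(nt), re(nt), jl(nt);
  for (int t = 0; t < nt; ++t) {
    Vec3 a(V(T(t, 0), 0), V(T(t, 0), 1), V(T(t, 0), 2));
    Vec3 b(V(T(t, 1), 0), V(T(t, 1), 1), V(T(t, 1), 2));
    Vec3 c(V(T(t, 2), 0), V(T(t, 2), 1), V(T(t, 2), 2));
    Vec3 e(V(T(t, 3), 0), V(T(t, 3), 1), V(T(t, 3), 2));
    tet_metrics_one(a, b, c, e, vol[t], re[t], jl[t]);
  }
  return List::create(_["volume"] = vol, _["radius_edge"] = re, _["joe_liu"] = jl);
}

// ---------------------------------------------------------------------------
// connected regions of same-label tets (shared-face adjacency)
// ---------------------------------------------------------------------------

namespace {
struct UF2 {
  std::vector<int> p;
  void init(int n) { p.resize(n); for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// exact face key: sorted (a,b,c) -> map[(a<<32)|b] list of (c, tet)
typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> FaceMap;

void build_face_map(const IntegerMatrix& T, FaceMap& fm) {
  int nt = T.nrow();
  const int FACES[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
  fm.reserve((size_t)nt * 2);
  for (int t = 0; t < nt; ++t)
    for (int f = 0; f < 4; ++f) {
      int a = T(t, FACES[f][0]), b = T(t, FACES[f][1]), c = T(t, FACES[f][2]);
      int v[3] = {a, b, c};
      std::sort(v, v + 3);
      uint64_t key = ((uint64_t)v[0] << 32) | (uint64_t)v[1];
      fm[key].emplace_back(v[2], t);
    }
}
}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_tet_regions(IntegerMatrix T, IntegerVector label) {
  int nt = T.nrow();
  FaceMap fm;
  build_face_map(T, fm);
  UF2 uf;
  uf.init(nt);
  for (auto& kv : fm) {
    auto& lst = kv.second;
    for (size_t i = 0; i < lst.size(); ++i)
      for (size_t j = i + 1; j < lst.size(); ++j)
        if (lst[i].first == lst[j].first &&
            label[lst[i].second] == label[lst[j].second])
          uf.unite(lst[i].second, lst[j].second);
  }
  std::unordered_map<int, int> relab;
  IntegerVector out(nt);
  for (int t = 0; t < nt; ++t) {
    int r = uf.find(t);
    auto it = relab.find(r);
    if (it == relab.end()) {
      int id = (int)relab.size() + 1;
      relab.emplace(r, id);
      out[t] = id;
    } else {
      out[t] = it->second;
    }
  }
  return out;
}

// Oriented boundary faces of the subset keep==TRUE (faces used exactly once
// by kept tets), wound outward.
// [[Rcpp::export]]
IntegerMatrix cpp_subset_boundary(IntegerMatrix T, LogicalVector keep) {
  int nt = T.nrow();
  const int FACES[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
  std::unordered_map<uint64_t, std::vector<std::array<int, 4>>> fm;
  fm.reserve((size_t)nt * 2);
  for (int t = 0; t < nt; ++t) {
    if (!keep[t]) continue;
    for (int f = 0; f < 4; ++f) {
      int a = T(t, FACES[f][0]), b = T(t, FACES[f][1]), c = T(t, FACES[f][2]);
      int v[3] = {a, b, c};
      std::sort(v, v + 3);
      uint64_t key = ((uint64_t)v[0] << 32) | (uint64_t)v[1];
      fm[key].push_back({v[2], a, b, c});
    }
  }
  std::vector<std::array<int, 3>> out;
  for (auto& kv : fm) {
    auto& lst = kv.second;
    for (size_t i = 0; i < lst.size(); ++i) {
      int cnt = 0;
      for (size_t j = 0; j < lst.size(); ++j)
        if (lst[j][0] == lst[i][0]) ++cnt;
      if (cnt == 1) out.push_back({lst[i][1], lst[i][2], lst[i][3]});
    }
  }
  IntegerMatrix F((int)out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) {
    F(i, 0) = out[i][0]; F(i, 1) = out[i][1]; F(i, 2) = out[i][2];
  }
  return F;
}

// ---------------------------------------------------------------------------
// local quality improvement: Laplacian moves accepted only when the worst
// incident radius-edge ratio improves and no incident element inverts.
// Vertices bound to a surface are reprojected onto it (closest point), so
// they slide tangentially and the boundary geometry is preserved.
// ---------------------------------------------------------------------------

namespace {

// minimal triangle-bin structure for closest-point queries
struct SurfBins {
  const NumericMatrix V;
  const IntegerMatrix F;
  double o[3], cell;
  int n[3];
  std::vector<std::vector<int>> bins;

  SurfBins(NumericMatrix V_, IntegerMatrix F_, double cell_size)
      : V(V_), F(F_) {
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < V.nrow(); ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], V(i, d));
        hi[d] = std::max(hi[d], V(i, d));
      }
    cell = cell_size;
    size_t tot = 1;
    for (int d = 0; d < 3; ++d) {
      o[d] = lo[d] - cell;
      n[d] = std::max(1, (int)((hi[d] - o[d]) / cell) + 2);
      tot *= (size_t)n[d];
    }
    bins.assign(tot, {});
    for (int t = 0; t < F.nrow(); ++t) {
      int i0[3], i1[3];
      for (int d = 0; d < 3; ++d) {
        double mn = 1e300, mx = -1e300;
        for (int c = 0; c < 3; ++c) {
          mn = std::min(mn, V(F(t, c), d));
          mx = std::max(mx, V(F(t, c), d));
        }
        i0[d] = clampi((int)((mn - o[d]) / cell), 0, n[d] - 1);
        i1[d] = clampi((int)((mx - o[d]) / cell), 0, n[d] - 1);
      }
      for (int k = i0[2]; k <= i1[2]; ++k)
        for (int j = i0[1]; j <= i1[1]; ++j)
          for (int i = i0[0]; i <= i1[0]; ++i)
            bins[(size_t)i + (size_t)n[0] * (j + (size_t)n[1] * k)].push_back(t);
    }
  }
  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

  bool project(const Vec3& p, double band, Vec3& out) const {
    int ci[3];
    for (int d = 0; d < 3; ++d) {
      double v = d == 0 ? p.x : (d == 1 ? p.y : p.z);
      ci[d] = clampi((int)((v - o[d]) / cell), 0, n[d] - 1);
    }
    int rmax = (int)(band / cell) + 1;
    double best = 1e300;
    for (int r = 0; r <= rmax; ++r) {
      double ring_lo = (r - 1) * cell;
      if (r > 0 && ring_lo > 0 && ring_lo * ring_lo > best) break;
      for (int dk = -r; dk <= r; ++dk)
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != r) continue;
            int i = ci[0] + di, j = ci[1] + dj, k = ci[2] + dk;
            if (i < 0 || i >= n[0] || j < 0 || j >= n[1] || k < 0 || k >= n[2])
              continue;
            for (int t : bins[(size_t)i + (size_t)n[0] * (j + (size_t)n[1] * k)]) {
              Vec3 a(V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2));
              Vec3 b(V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2));
              Vec3 c(V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2));
              Vec3 q = hm::closest_point_triangle(p, a, b, c);
              double d2 = hm::dist2(p, q);
              if (d2 < best) { best = d2; out = q; }
            }
          }
    }
    return best < 1e300;
  }
};

}  // namespace

// Edge-collapse mesh improvement.  Two phases per sweep: (1) a global
// short-edge pass that collapses every edge below `min_edge` (shortest
// first), which dissolves the clusters of tiny facets that snapping and
// cutting leave behind; (2) a targeted pass over elements whose radius-edge
// ratio exceeds `q_target`, trying their edges shortest-first.  A collapse is
// accepted only when it inverts nothing, creates no duplicate element,
// respects surface constraints (vertices bound to different surfaces are
// never merged; merging within one surface reprojects onto it), and leaves
// the local worst radius-edge ratio no worse than max(before, q_target).
// [[Rcpp::export]]
List cpp_collapse_slivers(NumericMatrix Vin, IntegerMatrix Tin,
                          IntegerVector label_in, IntegerVector vsurf_in,
                          List surfaces, double q_target, int max_sweeps,
                          double proj_band, double min_edge, double max_vol) {
  int nv = Vin.nrow(), nt = Tin.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<std::array<int, 4>> T(nt);
  for (int t = 0; t < nt; ++t) T[t] = {Tin(t, 0), Tin(t, 1), Tin(t, 2), Tin(t, 3)};
  std::vector<int> label(label_in.begin(), label_in.end());
  std::vector<int> vsurf(vsurf_in.begin(), vsurf_in.end());
  std::vector<char> alive(nt, 1);
  std::vector<SurfBins*> sb(surfaces.size(), nullptr);
  for (int s = 0; s < surfaces.size(); ++s) {
    List srf = surfaces[s];
    NumericMatrix SV = srf["vertices"];
    IntegerMatrix SF = srf["faces"];
    sb[s] = new SurfBins(SV, SF, proj_band);
  }
  std::vector<std::vector<int>> inc(nv);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c) inc[T[t][c]].push_back(t);
  auto re_of = [&](int t) {
    double vol, re, jl;
    tet_metrics_one(P[T[t][0]], P[T[t][1]], P[T[t][2]], P[T[t][3]], vol, re, jl);
    return re;
  };
  int n_collapsed = 0;
  std::vector<char> dead_vert(nv, 0);

  // attempt to collapse edge (a, b); returns true if performed.  Several
  // candidate merge positions are tried (projected midpoint / endpoints for
  // surface edges; midpoint / endpoints for interior edges).
  auto try_edge_at = [&](int a, int b, const Vec3& target, int snew) -> bool {
    std::vector<int> aff, dying, surv;
    for (int tt : inc[a]) if (alive[tt]) aff.push_back(tt);
    for (int tt : inc[b]) if (alive[tt]) aff.push_back(tt);
    std::sort(aff.begin(), aff.end());
    aff.erase(std::unique(aff.begin(), aff.end()), aff.end());
    bool edge_found = false;
    double old_worst = 0;
    for (int tt : aff) {
      old_worst = std::max(old_worst, re_of(tt));
      bool has_a = false, has_b = false;
      for (int c = 0; c < 4; ++c) {
        if (T[tt][c] == a) has_a = true;
        if (T[tt][c] == b) has_b = true;
      }
      if (has_a && has_b) { dying.push_back(tt); edge_found = true; }
      else surv.push_back(tt);
    }
    if (!edge_found || surv.empty()) return false;
    bool ok = true;
    double new_worst = 0;
    std::vector<std::array<int, 4>> newsets;
    for (int tt : surv) {
      Vec3 q[4];
      std::array<int, 4> ids;
      for (int c = 0; c < 4; ++c) {
        int vtx = T[tt][c];
        if (vtx == b) vtx = a;
        ids[c] = vtx;
        q[c] = (vtx == a) ? target : P[vtx];
      }
      double vol = hm::tet_signed_volume(q[0], q[1], q[2], q[3]);
      if (!(vol > 1e-13) || vol > max_vol) { ok = false; break; }
      double vv, re, jl;
      tet_metrics_one(q[0], q[1], q[2], q[3], vv, re, jl);
      new_worst = std::max(new_worst, re);
      std::sort(ids.begin(), ids.end());
      newsets.push_back(ids);
    }
    if (!ok) return false;
    if (new_worst > std::max(q_target, old_worst)) return false;
    std::sort(newsets.begin(), newsets.end());
    if (std::adjacent_find(newsets.begin(), newsets.end()) != newsets.end())
      return false;
    for (int tt : dying) alive[tt] = 0;
    for (int tt : surv)
      for (int c = 0; c < 4; ++c)
        if (T[tt][c] == b) T[tt][c] = a;
    for (int tt : inc[b]) inc[a].push_back(tt);
    inc[b].clear();
    dead_vert[b] = 1;
    P[a] = target;
    vsurf[a] = snew;
    ++n_collapsed;
    return true;
  };

  auto try_edge = [&](int a, int b) -> bool {
    if (a == b || dead_vert[a] || dead_vert[b]) return false;
    int sa = vsurf[a], sbv = vsurf[b];
    if (sa == -2 || sbv == -2) return false;
    if (sa == -1 && sbv == -1) {
      Vec3 mid = (P[a] + P[b]) * 0.5;
      return try_edge_at(a, b, mid, -1) || try_edge_at(a, b, P[a], -1) ||
             try_edge_at(a, b, P[b], -1);
    }
    if (sa >= 0 && sbv == -1) return try_edge_at(a, b, P[a], sa);
    if (sa == -1 && sbv >= 0) return try_edge_at(a, b, P[b], sbv);
    if (sa == sbv) {
      Vec3 mid = (P[a] + P[b]) * 0.5, proj;
      if (sb[sa]->project(mid, proj_band, proj) && try_edge_at(a, b, proj, sa))
        return true;
      return try_edge_at(a, b, P[a], sa) || try_edge_at(a, b, P[b], sa);
    }
    return false;  // spans two surfaces
  };

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int done = 0;
    // phase 1: global short-edge pass
    if (min_edge > 0) {
      std::vector<std::pair<double, std::pair<int, int>>> shorts;
      std::unordered_map<uint64_t, char> seen;
      for (int t = 0; t < nt; ++t) {
        if (!alive[t]) continue;
        for (int a = 0; a < 4; ++a)
          for (int b = a + 1; b < 4; ++b) {
            int va = T[t][a], vb = T[t][b];
            uint64_t key = hm::edge_key((uint64_t)va, (uint64_t)vb);
            if (!seen.emplace(key, 1).second) continue;
            double l2 = hm::dist2(P[va], P[vb]);
            if (l2 < min_edge * min_edge)
              shorts.emplace_back(l2, std::make_pair(va, vb));
          }
      }
      std::sort(shorts.begin(), shorts.end());
      for (auto& e : shorts)
        if (try_edge(e.second.first, e.second.second)) ++done;
    }
    // phase 2: elements above the radius-edge target
    std::vector<std::pair<double, int>> bad;
    for (int t = 0; t < nt; ++t) {
      if (!alive[t]) continue;
      double re = re_of(t);
      if (re > q_target) bad.emplace_back(-re, t);
    }
    std::sort(bad.begin(), bad.end());
    for (auto& pr : bad) {
      int t = pr.second;
      if (!alive[t] || re_of(t) <= q_target) continue;
      std::vector<std::pair<double, std::pair<int, int>>> edges;
      for (int a = 0; a < 4; ++a)
        for (int b = a + 1; b < 4; ++b)
          edges.emplace_back(hm::dist2(P[T[t][a]], P[T[t][b]]),
                             std::make_pair(T[t][a], T[t][b]));
      std::sort(edges.begin(), edges.end());
      for (auto& e : edges)
        if (try_edge(e.second.first, e.second.second)) { ++done; break; }
    }
    if (done == 0) break;
  }
  for (auto* p : sb) delete p;
  std::vector<int> keep;
  for (int t = 0; t < nt; ++t)
    if (alive[t]) keep.push_back(t);
  IntegerMatrix T2((int)keep.size(), 4);
  IntegerVector lab2((int)keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    for (int c = 0; c < 4; ++c) T2(i, c) = T[keep[i]][c];
    lab2[i] = label[keep[i]];
  }
  NumericMatrix V2(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  return List::create(_["vertices"] = V2, _["tets"] = T2, _["label"] = lab2,
                      _["vsurf"] = IntegerVector(vsurf.begin(), vsurf.end()),
                      _["n_collapsed"] = n_collapsed);
}

// Final polish: pattern search on the positions of vertices incident to the
// remaining above-target elements.  Each vertex is moved along +/- axis and
// diagonal directions with decreasing step, constrained vertices being
// reprojected onto their surface; a move is kept when it strictly lowers
// the worst radius-edge ratio among the vertex's incident elements.
// [[Rcpp::export]]
List cpp_polish_clusters(NumericMatrix Vin, IntegerMatrix T,
                         IntegerVector vsurf, List surfaces, double q_target,
                         int max_rounds, double proj_band, double step0) {
  int nv = Vin.nrow(), nt = T.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<SurfBins*> sb(surfaces.size(), nullptr);
  for (int s = 0; s < surfaces.size(); ++s) {
    List srf = surfaces[s];
    NumericMatrix SV = srf["vertices"];
    IntegerMatrix SF = srf["faces"];
    sb[s] = new SurfBins(SV, SF, proj_band);
  }
  std::vector<std::vector<int>> inc(nv);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c) inc[T(t, c)].push_back(t);
  auto worst_at = [&](int vtx) {
    double w = 0;
    for (int t : inc[vtx]) {
      double vol, re, jl;
      tet_metrics_one(P[T(t, 0)], P[T(t, 1)], P[T(t, 2)], P[T(t, 3)], vol, re,
                      jl);
      if (vol <= 0) return R_PosInf;
      w = std::max(w, re);
    }
    return w;
  };
  const double DIRS[14][3] = {
      {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1},
      {0.577, 0.577, 0.577}, {-0.577, 0.577, 0.577}, {0.577, -0.577, 0.577},
      {0.577, 0.577, -0.577}, {-0.577, -0.577, 0.577},
      {-0.577, 0.577, -0.577}, {0.577, -0.577, -0.577},
      {-0.577, -0.577, -0.577}};
  int n_improved = 0;
  for (int round = 0; round < max_rounds; ++round) {
    std::vector<int> verts;
    for (int t = 0; t < nt; ++t) {
      double vol, re, jl;
      tet_metrics_one(P[T(t, 0)], P[T(t, 1)], P[T(t, 2)], P[T(t, 3)], vol, re,
                      jl);
      if (re > q_target)
        for (int c = 0; c < 4; ++c) verts.push_back(T(t, c));
    }
    std::sort(verts.begin(), verts.end());
    verts.erase(std::unique(verts.begin(), verts.end()), verts.end());
    if (verts.empty()) break;
    int moved = 0;
    for (int v : verts) {
      if (vsurf[v] == -2) continue;
      bool any = true;
      while (any) {
        any = false;
        double cur = worst_at(v);
        if (cur <= q_target) break;
        Vec3 old = P[v];
        for (double step : {step0, step0 / 2, step0 / 4, step0 / 8}) {
          for (auto& d : DIRS) {
            Vec3 cand = old + Vec3(d[0], d[1], d[2]) * step;
            if (vsurf[v] >= 0) {
              Vec3 pr;
              if (!sb[vsurf[v]]->project(cand, proj_band, pr)) continue;
              cand = pr;
            }
            P[v] = cand;
            if (worst_at(v) < cur - 1e-12) {
              any = true;
              ++moved;
              break;
            }
            P[v] = old;
          }
          if (any) break;
        }
      }
    }
    n_improved += moved;
    if (moved == 0) break;
  }
  for (auto* p : sb) delete p;
  NumericMatrix V2(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  return List::create(_["vertices"] = V2, _["n_moved"] = n_improved);
}

// Edge removal (generalized 3-2 flip).  For an interior edge (a,b) whose
// star tets all carry one label, the star is re-triangulated as link-polygon
// fan x {a, b}, deleting the edge.  The fan apex minimizing the worst new
// radius-edge ratio is chosen; the move is accepted when every new element
// has positive volume, the star volume is conserved (which rules out folded
// fans), and the local worst ratio improves or falls within the target.
// [[Rcpp::export]]
List cpp_remove_edges(NumericMatrix Vin, IntegerMatrix Tin,
                      IntegerVector label_in, IntegerVector vsurf_in,
                      double q_target, int max_sweeps, double max_vol) {
  int nv = Vin.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<std::array<int, 4>> T(Tin.nrow());
  for (int t = 0; t < Tin.nrow(); ++t)
    T[t] = {Tin(t, 0), Tin(t, 1), Tin(t, 2), Tin(t, 3)};
  std::vector<int> label(label_in.begin(), label_in.end());
  std::vector<char> alive(T.size(), 1);
  std::vector<std::vector<int>> inc(nv);
  for (size_t t = 0; t < T.size(); ++t)
    for (int c = 0; c < 4; ++c) inc[T[t][c]].push_back((int)t);
  auto re_of = [&](const std::array<int, 4>& tet) {
    double vol, re, jl;
    tet_metrics_one(P[tet[0]], P[tet[1]], P[tet[2]], P[tet[3]], vol, re, jl);
    return re;
  };
  auto vol_of = [&](const std::array<int, 4>& tet) {
    return std::fabs(hm::tet_signed_volume(P[tet[0]], P[tet[1]], P[tet[2]],
                                           P[tet[3]]));
  };
  int n_removed = 0;

  auto try_remove = [&](int a, int b) -> bool {
    std::vector<int> star;
    for (int tt : inc[a]) {
      if (!alive[tt]) continue;
      bool ha = false, hb = false;
      for (int c = 0; c < 4; ++c) {
        if (T[tt][c] == a) ha = true;
        if (T[tt][c] == b) hb = true;
      }
      if (ha && hb) star.push_back(tt);
    }
    std::sort(star.begin(), star.end());
    star.erase(std::unique(star.begin(), star.end()), star.end());
    int k = (int)star.size();
    if (k < 3 || k > 8) return false;
    int lab0 = label[star[0]];
    for (int tt : star)
      if (label[tt] != lab0) return false;
    // link cycle
    std::unordered_map<int, std::vector<int>> adj;
    for (int tt : star) {
      int o[2], m = 0;
      for (int c = 0; c < 4; ++c)
        if (T[tt][c] != a && T[tt][c] != b) o[m++] = T[tt][c];
      adj[o[0]].push_back(o[1]);
      adj[o[1]].push_back(o[0]);
    }
    if ((int)adj.size() != k) return false;
    for (auto& kv : adj)
      if (kv.second.size() != 2) return false;  // boundary / non-manifold
    std::vector<int> cyc;
    int startv = adj.begin()->first, prev = -1, cur = startv;
    for (int step = 0; step < k; ++step) {
      cyc.push_back(cur);
      int nx = (adj[cur][0] == prev) ? adj[cur][1] : adj[cur][0];
      prev = cur;
      cur = nx;
    }
    if (cur != startv || (int)cyc.size() != k) return false;
    double old_worst = 0, old_vol = 0;
    for (int tt : star) {
      old_worst = std::max(old_worst, re_of(T[tt]));
      old_vol += vol_of(T[tt]);
    }
    // try every fan apex
    double best_worst = R_PosInf;
    std::vector<std::array<int, 4>> best;
    for (int ai = 0; ai < k; ++ai) {
      int apex = cyc[ai];
      std::vector<std::array<int, 4>> cand;
      double worst = 0, vsum = 0;
      bool ok = true;
      for (int j = 1; j + 1 < k && ok; ++j) {
        int p = cyc[(ai + j) % k], q = cyc[(ai + j + 1) % k];
        for (int side = 0; side < 2 && ok; ++side) {
          std::array<int, 4> tet = {apex, p, q, side == 0 ? a : b};
          double sv = hm::tet_signed_volume(P[tet[0]], P[tet[1]], P[tet[2]],
                                            P[tet[3]]);
          if (sv < 0) {
            std::swap(tet[1], tet[2]);
            sv = -sv;
          }
          if (!(sv > 1e-13) || sv > max_vol) { ok = false; break; }
          vsum += sv;
          worst = std::max(worst, re_of(tet));
          cand.push_back(tet);
        }
      }
      if (!ok) continue;
      if (std::fabs(vsum - old_vol) > 1e-7 * old_vol) continue;  // folded fan
      if (worst < best_worst) {
        best_worst = worst;
        best = cand;
      }
    }
    if (best.empty()) return false;
    if (best_worst > q_target && best_worst >= old_worst) return false;
    for (int tt : star) alive[tt] = 0;
    for (auto& tet : best) {
      int tn = (int)T.size();
      T.push_back(tet);
      label.push_back(lab0);
      alive.push_back(1);
      for (int c = 0; c < 4; ++c) inc[tet[c]].push_back(tn);
    }
    ++n_removed;
    return true;
  };

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    std::vector<std::pair<double, int>> bad;
    for (size_t t = 0; t < T.size(); ++t) {
      if (!alive[t]) continue;
      double re = re_of(T[t]);
      if (re > q_target) bad.emplace_back(-re, (int)t);
    }
    if (bad.empty()) break;
    std::sort(bad.begin(), bad.end());
    int done = 0;
    for (auto& prr : bad) {
      int t = prr.second;
      if (!alive[t] || re_of(T[t]) <= q_target) continue;
      // try all 6 edges, shortest first
      std::vector<std::pair<double, std::pair<int, int>>> edges;
      for (int x = 0; x < 4; ++x)
        for (int y = x + 1; y < 4; ++y)
          edges.emplace_back(hm::dist2(P[T[t][x]], P[T[t][y]]),
                             std::make_pair(T[t][x], T[t][y]));
      std::sort(edges.begin(), edges.end());
      for (auto& e : edges)
        if (try_remove(e.second.first, e.second.second)) { ++done; break; }
    }
    if (done == 0) break;
  }
  std::vector<int> keep;
  for (size_t t = 0; t < T.size(); ++t)
    if (alive[t]) keep.push_back((int)t);
  IntegerMatrix T2((int)keep.size(), 4);
  IntegerVector lab2((int)keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    for (int c = 0; c < 4; ++c) T2(i, c) = T[keep[i]][c];
    lab2[i] = label[keep[i]];
  }
  return List::create(_["vertices"] = Vin, _["tets"] = T2, _["label"] = lab2,
                      _["vsurf"] = vsurf_in, _["n_removed"] = n_removed);
}

// Long-edge split for elements above the radius-edge target.  An element
// whose boundary face is obtuse cannot be repaired by vertex motion (its
// circumradius is bounded below by the face circumradius), so the long edge
// is bisected; midpoints of interface edges are reprojected onto their
// surface.  Children are accepted when nothing inverts and the local worst
// radius-edge ratio does not regress beyond max(before, target).
// [[Rcpp::export]]
List cpp_split_long_edges(NumericMatrix Vin, IntegerMatrix Tin,
                          IntegerVector label_in, IntegerVector vsurf_in,
                          List surfaces, double q_target, int max_sweeps,
                          double proj_band) {
  std::vector<Vec3> P;
  for (int i = 0; i < Vin.nrow(); ++i)
    P.emplace_back(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<std::array<int, 4>> T(Tin.nrow());
  for (int t = 0; t < Tin.nrow(); ++t)
    T[t] = {Tin(t, 0), Tin(t, 1), Tin(t, 2), Tin(t, 3)};
  std::vector<int> label(label_in.begin(), label_in.end());
  std::vector<int> vsurf(vsurf_in.begin(), vsurf_in.end());
  std::vector<SurfBins*> sb(surfaces.size(), nullptr);
  for (int s = 0; s < surfaces.size(); ++s) {
    List srf = surfaces[s];
    NumericMatrix SV = srf["vertices"];
    IntegerMatrix SF = srf["faces"];
    sb[s] = new SurfBins(SV, SF, proj_band);
  }
  std::vector<std::vector<int>> inc;
  auto rebuild_inc = [&]() {
    inc.assign(P.size(), {});
    for (size_t t = 0; t < T.size(); ++t)
      for (int c = 0; c < 4; ++c) inc[T[t][c]].push_back((int)t);
  };
  rebuild_inc();
  auto re_of = [&](int t) {
    double vol, re, jl;
    tet_metrics_one(P[T[t][0]], P[T[t][1]], P[T[t][2]], P[T[t][3]], vol, re, jl);
    return re;
  };
  int n_split = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    std::vector<std::pair<double, int>> bad;
    for (size_t t = 0; t < T.size(); ++t) {
      double re = re_of((int)t);
      if (re > q_target) bad.emplace_back(-re, (int)t);
    }
    if (bad.empty()) break;
    std::sort(bad.begin(), bad.end());
    int done = 0;
    for (auto& prr : bad) {
      int t = prr.second;
      if (re_of(t) <= q_target) continue;
      // edges longest-first
      std::vector<std::pair<double, std::pair<int, int>>> edges;
      for (int a = 0; a < 4; ++a)
        for (int b = a + 1; b < 4; ++b)
          edges.emplace_back(-hm::dist2(P[T[t][a]], P[T[t][b]]),
                             std::make_pair(T[t][a], T[t][b]));
      std::sort(edges.begin(), edges.end());
      for (auto& e : edges) {
        int a = e.second.first, b = e.second.second;
        if (vsurf[a] == -2 || vsurf[b] == -2) continue;
        // star of the edge
        std::vector<int> star;
        for (int tt : inc[a]) {
          bool has_b = false, has_a = false;
          for (int c = 0; c < 4; ++c) {
            if (T[tt][c] == b) has_b = true;
            if (T[tt][c] == a) has_a = true;
          }
          if (has_a && has_b) star.push_back(tt);
        }
        std::sort(star.begin(), star.end());
        star.erase(std::unique(star.begin(), star.end()), star.end());
        if (star.empty()) continue;
        // does the edge lie on a boundary face?  faces (a,b,x) used once in
        // the star, or twice with different labels
        bool boundary = false;
        {
          std::unordered_map<int, std::pair<int, int>> fc;  // x -> count, label
          for (int tt : star)
            for (int c = 0; c < 4; ++c) {
              int x = T[tt][c];
              if (x == a || x == b) continue;
              auto it = fc.find(x);
              if (it == fc.end()) fc.emplace(x, std::make_pair(1, label[tt]));
              else {
                it->second.first++;
                if (it->second.second != label[tt]) boundary = true;
              }
            }
          // note: every face (a,b,x) appears in exactly 1 or 2 star tets
          for (auto& kv : fc)
            if (kv.second.first == 1) boundary = true;
        }
        Vec3 mid = (P[a] + P[b]) * 0.5;
        int snew = -1;
        if (boundary) {
          if (vsurf[a] < 0 || vsurf[a] != vsurf[b]) continue;
          Vec3 projd;
          if (!sb[vsurf[a]]->project(mid, proj_band, projd)) continue;
          mid = projd;
          snew = vsurf[a];
        }
        // simulate children
        double old_worst = 0, new_worst = 0;
        bool ok = true;
        for (int tt : star) old_worst = std::max(old_worst, re_of(tt));
        for (int tt : star) {
          for (int half = 0; half < 2 && ok; ++half) {
            Vec3 q[4];
            for (int c = 0; c < 4; ++c) {
              int vtx = T[tt][c];
              if (half == 0 && vtx == b) { q[c] = mid; continue; }
              if (half == 1 && vtx == a) { q[c] = mid; continue; }
              q[c] = P[vtx];
            }
            double vol = hm::tet_signed_volume(q[0], q[1], q[2], q[3]);
            if (!(vol > 1e-13)) { ok = false; break; }
            double vv, re, jl;
            tet_metrics_one(q[0], q[1], q[2], q[3], vv, re, jl);
            new_worst = std::max(new_worst, re);
          }
          if (!ok) break;
        }
        if (!ok || new_worst > std::max(q_target, old_worst)) continue;
        // perform
        int m = (int)P.size();
        P.push_back(mid);
        vsurf.push_back(snew);
        inc.emplace_back();
        for (int tt : star) {
          std::array<int, 4> child = T[tt];
          for (int c = 0; c < 4; ++c)
            if (T[tt][c] == b) T[tt][c] = m;  // tt becomes the a-side child
          for (int c = 0; c < 4; ++c)
            if (child[c] == a) child[c] = m;  // appended b-side child
          int tn = (int)T.size();
          T.push_back(child);
          label.push_back(label[tt]);
          for (int c = 0; c < 4; ++c) inc[T[tt][c]].push_back(tt);
          for (int c = 0; c < 4; ++c) inc[child[c]].push_back(tn);
        }
        ++n_split;
        ++done;
        break;
      }
    }
    if (done == 0) break;
  }
  for (auto* p : sb) delete p;
  NumericMatrix V2((int)P.size(), 3);
  for (size_t i = 0; i < P.size(); ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  IntegerMatrix T2((int)T.size(), 4);
  for (size_t t = 0; t < T.size(); ++t)
    for (int c = 0; c < 4; ++c) T2(t, c) = T[t][c];
  return List::create(_["vertices"] = V2, _["tets"] = T2,
                      _["label"] = IntegerVector(label.begin(), label.end()),
                      _["vsurf"] = IntegerVector(vsurf.begin(), vsurf.end()),
                      _["n_split"] = n_split);
}

// vsurf: -1 = free interior vertex, s >= 0 = bound to surfaces[[s+1]],
// -2 = frozen.  surfaces: list of list(vertices, faces).
// [[Rcpp::export]]
List cpp_improve_quality(NumericMatrix V, IntegerMatrix T, IntegerVector vsurf,
                         List surfaces, double q_target, int max_sweeps,
                         double proj_band) {
  int nv = V.nrow(), nt = T.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  std::vector<SurfBins*> sb(surfaces.size(), nullptr);
  for (int s = 0; s < surfaces.size(); ++s) {
    List srf = surfaces[s];
    NumericMatrix SV = srf["vertices"];
    IntegerMatrix SF = srf["faces"];
    sb[s] = new SurfBins(SV, SF, proj_band);
  }
  std::vector<std::vector<int>> inc(nv);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 4; ++c) inc[T(t, c)].push_back(t);
  auto worst_re = [&](int vtx) {
    double w = 0;
    for (int t : inc[vtx]) {
      double vol, re, jl;
      tet_metrics_one(P[T(t, 0)], P[T(t, 1)], P[T(t, 2)], P[T(t, 3)], vol, re, jl);
      if (vol <= 0) return R_PosInf;
      w = std::max(w, re);
    }
    return w;
  };
  int n_moved = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    std::vector<char> flag(nv, 0);
    int nbad = 0;
    for (int t = 0; t < nt; ++t) {
      double vol, re, jl;
      tet_metrics_one(P[T(t, 0)], P[T(t, 1)], P[T(t, 2)], P[T(t, 3)], vol, re, jl);
      if (re > q_target) {
        ++nbad;
        for (int c = 0; c < 4; ++c) flag[T(t, c)] = 1;
      }
    }
    if (nbad == 0) break;
    int moved = 0;
    for (int i = 0; i < nv; ++i) {
      if (!flag[i] || vsurf[i] == -2) continue;
      Vec3 cen(0, 0, 0);
      int n = 0;
      for (int t : inc[i])
        for (int c = 0; c < 4; ++c) {
          if (T(t, c) == i) continue;
          cen = cen + P[T(t, c)];
          ++n;
        }
      if (n == 0) continue;
      cen = cen * (1.0 / n);
      double before = worst_re(i);
      Vec3 old = P[i];
      bool did = false;
      for (double step : {1.0, 0.5, 0.25}) {
        Vec3 cand = old + (cen - old) * step;
        if (vsurf[i] >= 0) {
          Vec3 proj;
          if (!sb[vsurf[i]]->project(cand, proj_band, proj)) continue;
          cand = proj;
        }
        P[i] = cand;
        if (worst_re(i) < before) { did = true; break; }
        P[i] = old;
      }
      if (did) ++moved;
    }
    n_moved += moved;
    if (moved == 0) break;
  }
  for (auto* p : sb) delete p;
  NumericMatrix V2(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  return List::create(_["vertices"] = V2, _["n_moved"] = n_moved);
}
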