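#include <Rcpp.h>
#include <queue>
#include <set>
#include <unordered_map>
#include <algorithm>
#include "geomutil.h"
using namespace Rcpp;
using hm::Vec3;

// Quadric-error-metric edge-collapse decimation for closed manifold triangle
// meshes.  Candidate positions per collapse are the two endpoints, the
// midpoint, and the quadric-optimal point; collapses that violate the link
// condition or flip a face normal are rejected, which preserves closedness
// and manifoldness.

namespace {

struct Quadric {
  double m[10];  // symmetric 4x4: xx xy xz xw yy yz yw zz zw ww
  Quadric() { std::fill(m, m + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w) {
    m[0] += w * a * a; m[1] += w * a * b; m[2] += w * a * c; m[3] += w * a * d;
    m[4] += w * b * b; m[5] += w * b * c; m[6] += w * b * d;
    m[7] += w * c * c; m[8] += w * c * d; m[9] += w * d * d;
  }
  void add(const Quadric& o) {
    for (int i = 0; i < 10; ++i) m[i] += o.m[i];
  }
  double eval(const Vec3& p) const {
    return m[0] * p.x * p.x + 2 * m[1] * p.x * p.y + 2 * m[2] * p.x * p.z +
           2 * m[3] * p.x + m[4] * p.y * p.y + 2 * m[5] * p.y * p.z +
           2 * m[6] * p.y + m[7] * p.z * p.z + 2 * m[8] * p.z + m[9];
  }
  bool optimal(Vec3& out) const {
    double A[3][3] = {{m[0], m[1], m[2]}, {m[1], m[4], m[5]}, {m[2], m[5], m[7]}};
    double b[3] = {-m[3], -m[6], -m[8]};
    double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                 A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                 A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    if (std::fabs(det) < 1e-12) return false;
    out.x = (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
             A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
             A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2])) / det;
    out.y = (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
             b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
             A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0])) / det;
    out.z = (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
             A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
             b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
    return true;
  }
};

struct PQItem {
  double cost;
  int a, b;          // a < b
  uint64_t stamp;    // version sum when pushed
  bool operator<(const PQItem& o) const { return cost > o.cost; }  // min-heap
};

}  // namespace

// target_edges: stop when this many edges remain.  min_length > 0 switches
// to cleanup mode: only edges shorter than min_length are collapsed (cost =
// length) and the pass ends when none remain.
// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_edges,
                  double min_length = 0.0) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<Vec3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = Vec3(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<std::array<int, 3>> F(nf);
  for (int t = 0; t < nf; ++t) F[t] = {Fin(t, 0), Fin(t, 1), Fin(t, 2)};
  std::vector<bool> face_alive(nf, true), vert_alive(nv, true);
  std::vector<std::set<int>> vfaces(nv);
  for (int t = 0; t < nf; ++t)
    for (int c = 0; c < 3; ++c) vfaces[F[t][c]].insert(t);

  std::vector<Quadric> Q(nv);
  for (int t = 0; t < nf; ++t) {
    Vec3 a = P[F[t][0]], b = P[F[t][1]], c = P[F[t][2]];
    Vec3 n = hm::cross(b - a, c - a);
    double area2 = hm::norm(n);
    if (area2 < 1e-300) continue;
    Vec3 u = n * (1.0 / area2);
    double d = -hm::dot(u, a);
    for (int cc = 0; cc < 3; ++cc)
      Q[F[t][cc]].add_plane(u.x, u.y, u.z, d, area2 / 2.0);
  }

  std::vector<uint64_t> version(nv, 0);
  auto neighbors = [&](int v) {
    std::set<int> nb;
    for (int t : vfaces[v])
      for (int c = 0; c < 3; ++c)
        if (F[t][c] != v) nb.insert(F[t][c]);
    return nb;
  };

  auto edge_cost = [&](int a, int b, Vec3& best_pos) {
    if (min_length > 0) {
      best_pos = (P[a] + P[b]) * 0.5;
      return hm::norm(P[a] - P[b]);
    }
    Quadric q = Q[a];
    q.add(Q[b]);
    Vec3 cands[4];
    int nc = 0;
    Vec3 opt;
    if (q.optimal(opt)) cands[nc++] = opt;
    cands[nc++] = (P[a] + P[b]) * 0.5;
    cands[nc++] = P[a];
    cands[nc++] = P[b];
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < nc; ++i) {
      double e = q.eval(cands[i]);
      if (e < best) { best = e; best_pos = cands[i]; }
    }
    return best;
  };

  std::priority_queue<PQItem> pq;
  auto push_edge = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    Vec3 pos;
    double c = edge_cost(a, b, pos);
    pq.push({c, a, b, version[a] + version[b]});
  };
  {
    std::set<uint64_t> seen;
    for (int t = 0; t < nf; ++t)
      for (int c = 0; c < 3; ++c) {
        int a = F[t][c], b = F[t][(c + 1) % 3];
        uint64_t k = hm::edge_key(a, b);
        if (seen.insert(k).second) push_edge(a, b);
      }
  }

  int edges_alive = 3 * nf / 2;
  int faces_alive = nf;

  auto try_collapse = [&](int a, int b) -> bool {
    // link condition: common neighbors must be exactly the two opposite verts
    std::set<int> na = neighbors(a), nb = neighbors(b);
    std::vector<int> common;
    std::set_intersection(na.begin(), na.end(), nb.begin(), nb.end(),
                          std::back_inserter(common));
    if (common.size() != 2) return false;
    Vec3 pos;
    edge_cost(a, b, pos);
    // normal-flip / degeneracy check on surviving faces
    for (int pass = 0; pass < 2; ++pass) {
      int v = pass == 0 ? a : b;
      for (int t : vfaces[v]) {
        bool has_a = false, has_b = false;
        for (int c = 0; c < 3; ++c) {
          if (F[t][c] == a) has_a = true;
          if (F[t][c] == b) has_b = true;
        }
        if (has_a && has_b) continue;  // face dies
        Vec3 p[3], pn[3];
        for (int c = 0; c < 3; ++c) {
          p[c] = P[F[t][c]];
          pn[c] = (F[t][c] == v) ? pos : p[c];
        }
        Vec3 n0 = hm::cross(p[1] - p[0], p[2] - p[0]);
        Vec3 n1 = hm::cross(pn[1] - pn[0], pn[2] - pn[0]);
        // a face that is already (near-)degenerate carries no orientation
        // or shape information: let cleanup collapse through it
        bool junk = min_length > 0 && hm::norm(n0) < 1e-6;
        if (!junk && hm::dot(n0, n1) <= 1e-12 * hm::dot(n0, n0)) return false;
        // shape guard: refuse near-collinear survivors (circumradius much
        // larger than the longest edge), which would degenerate the surface
        double la = hm::norm(pn[1] - pn[0]), lb = hm::norm(pn[2] - pn[1]),
               lc = hm::norm(pn[0] - pn[2]);
        double K = hm::norm(n1) / 2.0;
        double lmax = std::max({la, lb, lc});
        if (!junk && (K < 1e-12 || la * lb * lc / (4.0 * K) > 10.0 * lmax))
          return false;
      }
    }
    // perform: b merges into a
    std::vector<int> dying;
    for (int t : vfaces[a])
      if (vfaces[b].count(t)) dying.push_back(t);
    if (dying.size() != 2) return false;
    for (int t : dying) {
      face_alive[t] = false;
      for (int c = 0; c < 3; ++c) vfaces[F[t][c]].erase(t);
      --faces_alive;
    }
    for (int t : std::vector<int>(vfaces[b].begin(), vfaces[b].end())) {
      for (int c = 0; c < 3; ++c)
        if (F[t][c] == b) F[t][c] = a;
      vfaces[b].erase(t);
      vfaces[a].insert(t);
    }
    P[a] = pos;
    Q[a].add(Q[b]);
    vert_alive[b] = false;
    version[a]++;
    version[b]++;
    edges_alive -= 3;
    for (int nbv : neighbors(a)) push_edge(a, nbv);
    return true;
  };

  while (!pq.empty()) {
    if (min_length > 0) {
      if (pq.top().cost >= min_length) break;
    } else {
      if (edges_alive <= target_edges) break;
    }
    PQItem it = pq.top();
    pq.pop();
    if (!vert_alive[it.a] || !vert_alive[it.b]) continue;
    if (version[it.a] + version[it.b] != it.stamp) continue;
    if (faces_alive <= 4) break;
    try_collapse(it.a, it.b);
  }

  // compact
  std::vector<int> remap(nv, -1);
  int nv2 = 0;
  for (int i = 0; i < nv; ++i)
    if (vert_alive[i]) remap[i] = nv2++;
  NumericMatrix V2(nv2, 3);
  for (int i = 0; i < nv; ++i)
    if (remap[i] >= 0) {
      V2(remap[i], 0) = P[i].x; V2(remap[i], 1) = P[i].y; V2(remap[i], 2) = P[i].z;
    }
  std::vector<std::array<int, 3>> fa;
  for (int t = 0; t < nf; ++t)
    if (face_alive[t]) fa.push_back({remap[F[t][0]], remap[F[t][1]], remap[F[t][2]]});
  IntegerMatrix F2((int)fa.size(), 3);
  for (size_t t = 0; t < fa.size(); ++t) {
    F2(t, 0) = fa[t][0]; F2(t, 1) = fa[t][1]; F2(t, 2) = fa[t][2];
  }
  return List::create(_["vertices"] = V2, _["faces"] = F2,
                      _["edges"] = edges_alive);
}
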