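#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "geomutil.h"
using namespace Rcpp;
using hm::Vec3;

// ---------------------------------------------------------------------------
// Shared helpers: triangle soup accessors and an xy binning structure used to
// accelerate vertical (+z) parity ray casts.
// ---------------------------------------------------------------------------

namespace {

struct TriSoup {
  const double* V;  // nv x 3, column-major
  const int* F;     // nf x 3, column-major, 0-based
  int nv, nf;
  Vec3 vert(int i) const { return Vec3(V[i], V[i + nv], V[i + 2 * nv]); }
  void tri(int t, Vec3& a, Vec3& b, Vec3& c) const {
    a = vert(F[t]); b = vert(F[t + nf]); c = vert(F[t + 2 * nf]);
  }
};

struct XYBins {
  double x0, y0, cell;
  int bx, by;
  std::vector<std::vector<int>> bins;

  void build(const TriSoup& s, double cell_size) {
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
    for (int i = 0; i < s.nv; ++i) {
      xmin = std::min(xmin, s.V[i]); xmax = std::max(xmax, s.V[i]);
      ymin = std::min(ymin, s.V[i + s.nv]); ymax = std::max(ymax, s.V[i + s.nv]);
    }
    cell = cell_size;
    x0 = xmin - cell; y0 = ymin - cell;
    bx = std::max(1, (int)((xmax - x0) / cell) + 2);
    by = std::max(1, (int)((ymax - y0) / cell) + 2);
    bins.assign((size_t)bx * by, {});
    Vec3 a, b, c;
    for (int t = 0; t < s.nf; ++t) {
      s.tri(t, a, b, c);
      int i0 = clampi((int)((std::min({a.x, b.x, c.x}) - x0) / cell), 0, bx - 1);
      int i1 = clampi((int)((std::max({a.x, b.x, c.x}) - x0) / cell), 0, bx - 1);
      int j0 = clampi((int)((std::min({a.y, b.y, c.y}) - y0) / cell), 0, by - 1);
      int j1 = clampi((int)((std::max({a.y, b.y, c.y}) - y0) / cell), 0, by - 1);
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          bins[(size_t)i + (size_t)bx * j].push_back(t);
    }
  }
  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }
  const std::vector<int>* column(double x, double y) const {
    int i = (int)((x - x0) / cell), j = (int)((y - y0) / cell);
    if (i < 0 || i >= bx || j < 0 || j >= by) return nullptr;
    return &bins[(size_t)i + (size_t)bx * j];
  }
};

// Deterministic perturbation schedule for parity rays (fractions of `scale`).
static const double PERTURB[6][2] = {
  {0.0, 0.0}, {1.3e-5, 0.7e-5}, {-0.9e-5, 1.7e-5},
  {2.3e-5, -1.1e-5}, {-1.9e-5, -2.9e-5}, {3.1e-5, 3.7e-5}};

// Count +z crossings above z for a point; returns -1 if no robust answer at
// this perturbation level.
int crossings_above(const TriSoup& s, const XYBins& bins, double x, double y,
                    double z, double scale, int pert) {
  double px = x + PERTURB[pert][0] * scale, py = y + PERTURB[pert][1] * scale;
  const std::vector<int>* col = bins.column(px, py);
  if (!col) return 0;
  Vec3 orig(px, py, z), dir(0, 0, 1);
  Vec3 a, b, c;
  int n = 0;
  for (int t : *col) {
    s.tri(t, a, b, c);
    // quick reject in z: all below
    if (a.z < z && b.z < z && c.z < z) continue;
    double tt;
    bool robust = true;
    bool hit = hm::ray_triangle(orig, dir, a, b, c, tt, robust);
    if (!robust) return -1;
    if (hit) ++n;
  }
  return n;
}

bool point_inside(const TriSoup& s, const XYBins& bins, double x, double y,
                  double z, double scale) {
  for (int p = 0; p < 6; ++p) {
    int n = crossings_above(s, bins, x, y, z, scale, p);
    if (n >= 0) return (n % 2) == 1;
  }
  // all perturbations hit degeneracies: resolve by nearest-triangle normal
  return false;
}

double mesh_scale(const TriSoup& s) {
  double xmin = 1e300, xmax = -1e300;
  for (int i = 0; i < s.nv; ++i) {
    xmin = std::min(xmin, s.V[i]);
    xmax = std::max(xmax, s.V[i]);
  }
  double d = xmax - xmin;
  return d > 0 ? d : 1.0;
}

double mean_edge(const TriSoup& s) {
  double tot = 0;
  Vec3 a, b, c;
  int n = std::min(s.nf, 2000);
  for (int t = 0; t < n; ++t) {
    s.tri(t, a, b, c);
    tot += hm::norm(b - a) + hm::norm(c - b) + hm::norm(a - c);
  }
  return n ? tot / (3.0 * n) : 1.0;
}

}  // namespace

// ---------------------------------------------------------------------------
// point containment
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriSoup s{V.begin(), F.begin(), (int)V.nrow(), (int)F.nrow()};
  XYBins bins;
  bins.build(s, std::max(mean_edge(s) * 2.0, 1e-6));
  double scale = mesh_scale(s);
  int n = P.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = point_inside(s, bins, P(i, 0), P(i, 1), P(i, 2), scale);
  return out;
}

// Voxel rasterization: voxel center (i,j,k) -> origin + (i sx, j sy, k sz).
// One parity ray per (x,y) column; crossing depths mark inside intervals.
// [[Rcpp::export]]
IntegerVector cpp_rasterize(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                            NumericVector origin, NumericVector spacing) {
  TriSoup s{V.begin(), F.begin(), (int)V.nrow(), (int)F.nrow()};
  XYBins bins;
  bins.build(s, std::max(mean_edge(s) * 2.0, 1e-6));
  double scale = mesh_scale(s);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((size_t)nx * ny * nz);
  Vec3 a, b, c;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double x = origin[0] + i * spacing[0], y = origin[1] + j * spacing[1];
      std::vector<double> zs;
      bool ok = false;
      for (int p = 0; p < 6 && !ok; ++p) {
        zs.clear();
        ok = true;
        double px = x + PERTURB[p][0] * scale, py = y + PERTURB[p][1] * scale;
        const std::vector<int>* col = bins.column(px, py);
        if (!col) break;
        Vec3 orig(px, py, origin[2] - spacing[2] * 2.0 - 1.0), dir(0, 0, 1);
        for (int t : *col) {
          s.tri(t, a, b, c);
          double tt;
          bool robust = true;
          bool hit = hm::ray_triangle(orig, dir, a, b, c, tt, robust);
          if (!robust) { ok = false; break; }
          if (hit) zs.push_back(orig.z + tt);
        }
      }
      if (!ok) zs.clear();
      std::sort(zs.begin(), zs.end());
      for (int k = 0; k < nz; ++k) {
        double z = origin[2] + k * spacing[2];
        size_t ncross = zs.end() - std::upper_bound(zs.begin(), zs.end(), z);
        out[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = (ncross % 2) == 1;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// signed distance with closest points (narrow band)
// ---------------------------------------------------------------------------

namespace {

struct Bins3D {
  double o[3], cell;
  int n[3];
  std::vector<std::vector<int>> bins;

  void build(const TriSoup& s, double cell_size) {
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < s.nv; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = s.V[i + d * s.nv];
        lo[d] = std::min(lo[d], v);
        hi[d] = std::max(hi[d], v);
      }
    cell = cell_size;
    size_t tot = 1;
    for (int d = 0; d < 3; ++d) {
      o[d] = lo[d] - cell;
      n[d] = std::max(1, (int)((hi[d] - o[d]) / cell) + 2);
      tot *= (size_t)n[d];
    }
    bins.assign(tot, {});
    Vec3 a, b, c;
    for (int t = 0; t < s.nf; ++t) {
      s.tri(t, a, b, c);
      int i0[3], i1[3];
      double mn[3] = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}),
                      std::min({a.z, b.z, c.z})};
      double mx[3] = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}),
                      std::max({a.z, b.z, c.z})};
      for (int d = 0; d < 3; ++d) {
        i0[d] = XYBins::clampi((int)((mn[d] - o[d]) / cell), 0, n[d] - 1);
        i1[d] = XYBins::clampi((int)((mx[d] - o[d]) / cell), 0, n[d] - 1);
      }
      for (int k = i0[2]; k <= i1[2]; ++k)
        for (int j = i0[1]; j <= i1[1]; ++j)
          for (int i = i0[0]; i <= i1[0]; ++i)
            bins[(size_t)i + (size_t)n[0] * (j + (size_t)n[1] * k)].push_back(t);
    }
  }

  // closest triangle point within `band` of p; returns squared distance or
  // a value > band^2 if none.
  double closest(const TriSoup& s, const Vec3& p, double band, Vec3& cp) const {
    int ci[3];
    for (int d = 0; d < 3; ++d) {
      double v = d == 0 ? p.x : (d == 1 ? p.y : p.z);
      ci[d] = XYBins::clampi((int)((v - o[d]) / cell), 0, n[d] - 1);
    }
    int rmax = (int)(band / cell) + 1;
    double best = band * band * 4.0 + 1.0;
    Vec3 a, b, c;
    for (int r = 0; r <= rmax; ++r) {
      double ring_lo = (r - 1) * cell;  // lower bound on distance to ring r
      if (r > 0 && ring_lo > 0 && ring_lo * ring_lo > best) break;
      for (int dk = -r; dk <= r; ++dk)
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != r) continue;
            int i = ci[0] + di, j = ci[1] + dj, k = ci[2] + dk;
            if (i < 0 || i >= n[0] || j < 0 || j >= n[1] || k < 0 || k >= n[2]) continue;
            for (int t : bins[(size_t)i + (size_t)n[0] * (j + (size_t)n[1] * k)]) {
              s.tri(t, a, b, c);
              Vec3 q = hm::closest_point_triangle(p, a, b, c);
              double d2 = hm::dist2(p, q);
              if (d2 < best) { best = d2; cp = q; }
            }
          }
    }
    return best;
  }
};

}  // namespace

// Signed distance (negative inside) to a closed surface for arbitrary points.
// Exact magnitude within `band`; +/- band outside the band.  Also returns
// closest surface points (NaN beyond band).
// [[Rcpp::export]]
List cpp_signed_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                         double band) {
  TriSoup s{V.begin(), F.begin(), (int)V.nrow(), (int)F.nrow()};
  double me = mean_edge(s);
  XYBins xy;
  xy.build(s, std::max(me * 2.0, 1e-6));
  Bins3D b3;
  b3.build(s, std::max({me, band / 4.0, 1e-6}));
  double scale = mesh_scale(s);
  int np = P.nrow();
  NumericVector d(np);
  NumericMatrix CP(np, 3);
  std::fill(CP.begin(), CP.end(), NA_REAL);
  for (int i = 0; i < np; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    Vec3 cp;
    double d2 = b3.closest(s, p, band, cp);
    double mag = std::sqrt(d2);
    bool in = point_inside(s, xy, p.x, p.y, p.z, scale);
    if (mag <= band) {
      d[i] = in ? -mag : mag;
      CP(i, 0) = cp.x; CP(i, 1) = cp.y; CP(i, 2) = cp.z;
    } else {
      d[i] = in ? -band : band;
    }
  }
  return List::create(_["distance"] = d, _["closest"] = CP);
}

// ---------------------------------------------------------------------------
// nearest-node distances (surface error metric)
// ---------------------------------------------------------------------------

// For each row of A, distance to the nearest row of B (node-to-node).
// [[Rcpp::export]]
NumericVector cpp_nearest_node_dist(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  // bin B points on a grid sized to ~1 point per cell
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < nb; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], B(i, d));
      hi[d] = std::max(hi[d], B(i, d));
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double cell = ext / std::max(4.0, std::cbrt((double)nb));
  int n[3];
  size_t tot = 1;
  for (int d = 0; d < 3; ++d) {
    lo[d] -= cell;
    n[d] = std::max(1, (int)((hi[d] - lo[d]) / cell) + 2);
    tot *= (size_t)n[d];
  }
  std::vector<std::vector<int>> bins(tot);
  for (int i = 0; i < nb; ++i) {
    int ci[3];
    for (int d = 0; d < 3; ++d)
      ci[d] = XYBins::clampi((int)((B(i, d) - lo[d]) / cell), 0, n[d] - 1);
    bins[(size_t)ci[0] + (size_t)n[0] * (ci[1] + (size_t)n[1] * ci[2])].push_back(i);
  }
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    Vec3 p(A(i, 0), A(i, 1), A(i, 2));
    int ci[3];
    for (int d = 0; d < 3; ++d) {
      double v = d == 0 ? p.x : (d == 1 ? p.y : p.z);
      ci[d] = XYBins::clampi((int)((v - lo[d]) / cell), 0, n[d] - 1);
    }
    double best = 1e300;
    int rmax = std::max({n[0], n[1], n[2]});
    for (int r = 0; r < rmax; ++r) {
      double ring_lo = (r - 1) * cell;
      if (r > 0 && ring_lo > 0 && ring_lo * ring_lo > best) break;
      for (int dk = -r; dk <= r; ++dk)
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != r) continue;
            int a = ci[0] + di, b = ci[1] + dj, c = ci[2] + dk;
            if (a < 0 || a >= n[0] || b < 0 || b >= n[1] || c < 0 || c >= n[2]) continue;
            for (int idx : bins[(size_t)a + (size_t)n[0] * (b + (size_t)n[1] * c)]) {
              double d2 = hm::dist2(p, Vec3(B(idx, 0), B(idx, 1), B(idx, 2)));
              if (d2 < best) best = d2;
            }
          }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// triangle-triangle intersection testing
// ---------------------------------------------------------------------------

namespace {

// Segment-triangle intersection test used pairwise on triangle edges: two
// triangles intersect iff an edge of one crosses the interior of the other
// (coplanar overlaps are not produced by the surfaces we test and near-touch
// cases are controlled by `tol`).
bool seg_tri(const Vec3& p, const Vec3& q, const Vec3& a, const Vec3& b,
             const Vec3& c, double tol) {
  Vec3 n = hm::cross(b - a, c - a);
  double da = hm::dot(n, p - a), db = hm::dot(n, q - a);
  if ((da > tol && db > tol) || (da < -tol && db < -tol)) return false;
  double denom = da - db;
  if (std::fabs(denom) < 1e-300) return false;
  double t = da / denom;
  if (t < 0.0 || t > 1.0) return false;
  Vec3 x = p + (q - p) * t;
  // barycentric containment with strict margin
  double n2 = hm::dot(n, n);
  if (n2 < 1e-300) return false;
  Vec3 w = x - a;
  double d00 = hm::dot(b - a, b - a), d01 = hm::dot(b - a, c - a),
         d11 = hm::dot(c - a, c - a), d20 = hm::dot(w, b - a), d21 = hm::dot(w, c - a);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < 1e-300) return false;
  double v = (d11 * d20 - d01 * d21) / den;
  double u = (d00 * d21 - d01 * d20) / den;
  double m = tol / std::sqrt(std::max(d00, d11));
  return v > m && u > m && (1.0 - v - u) > m;
}

bool tri_tri(const Vec3& a0, const Vec3& a1, const Vec3& a2, const Vec3& b0,
             const Vec3& b1, const Vec3& b2, double tol) {
  return seg_tri(a0, a1, b0, b1, b2, tol) || seg_tri(a1, a2, b0, b1, b2, tol) ||
         seg_tri(a2, a0, b0, b1, b2, tol) || seg_tri(b0, b1, a0, a1, a2, tol) ||
         seg_tri(b1, b2, a0, a1, a2, tol) || seg_tri(b2, b0, a0, a1, a2, tol);
}

}  // namespace

// Count intersecting triangle pairs between two surfaces (or within one if
// self = TRUE, skipping pairs that share a vertex).  Candidate pairs come from
// a uniform spatial hash.  Returns the number found (capped) and the first
// offending pair (1-based), if any.
// [[Rcpp::export]]
List cpp_tri_intersections(NumericMatrix V1, IntegerMatrix F1, NumericMatrix V2,
                           IntegerMatrix F2, bool self, double tol) {
  TriSoup s1{V1.begin(), F1.begin(), (int)V1.nrow(), (int)F1.nrow()};
  TriSoup s2{V2.begin(), F2.begin(), (int)V2.nrow(), (int)F2.nrow()};
  double cell = std::max({mean_edge(s1), mean_edge(s2), 1e-9}) * 1.5;
  Bins3D b3;
  b3.build(s2, cell);
  Vec3 a0, a1, a2, b0, b1, b2;
  int count = 0, first_i = NA_INTEGER, first_j = NA_INTEGER;
  for (int t = 0; t < s1.nf; ++t) {
    s1.tri(t, a0, a1, a2);
    double mn[3] = {std::min({a0.x, a1.x, a2.x}), std::min({a0.y, a1.y, a2.y}),
                    std::min({a0.z, a1.z, a2.z})};
    double mx[3] = {std::max({a0.x, a1.x, a2.x}), std::max({a0.y, a1.y, a2.y}),
                    std::max({a0.z, a1.z, a2.z})};
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = XYBins::clampi((int)((mn[d] - b3.o[d]) / b3.cell), 0, b3.n[d] - 1);
      i1[d] = XYBins::clampi((int)((mx[d] - b3.o[d]) / b3.cell), 0, b3.n[d] - 1);
    }
    std::vector<int> cand;
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i)
          for (int u : b3.bins[(size_t)i + (size_t)b3.n[0] * (j + (size_t)b3.n[1] * k)])
            cand.push_back(u);
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int u : cand) {
      if (self) {
        if (u <= t) continue;
        bool share = false;
        for (int x = 0; x < 3 && !share; ++x)
          for (int y = 0; y < 3; ++y)
            if (F1(t, x) == F2(u, y)) { share = true; break; }
        if (share) continue;
      }
      s2.tri(u, b0, b1, b2);
      if (tri_tri(a0, a1, a2, b0, b1, b2, tol)) {
        if (count == 0) { first_i = t + 1; first_j = u + 1; }
        ++count;
        if (count >= 100) {
          return List::create(_["count"] = count, _["first"] =
            IntegerVector::create(first_i, first_j));
        }
      }
    }
  }
  return List::create(_["count"] = count,
                      _["first"] = IntegerVector::create(first_i, first_j));
}

// ---------------------------------------------------------------------------
// connected components of a triangle mesh (by shared vertices)
// ---------------------------------------------------------------------------

namespace {
struct UF {
  std::vector<int> p;
  void init(int n) { p.resize(n); for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};
}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nv) {
  UF uf;
  uf.init(nv);
  int nf = F.nrow();
  for (int t = 0; t < nf; ++t) {
    uf.unite(F(t, 0), F(t, 1));
    uf.unite(F(t, 0), F(t, 2));
  }
  std::unordered_map<int, int> relab;
  IntegerVector comp(nf);
  for (int t = 0; t < nf; ++t) {
    int r = uf.find(F(t, 0));
    auto it = relab.find(r);
    if (it == relab.end()) {
      int id = (int)relab.size() + 1;
      relab.emplace(r, id);
      comp[t] = id;
    } else {
      comp[t] = it->second;
    }
  }
  return comp;
}
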