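#include <Rcpp.h>
#include <unordered_map>
#include "geomutil.h"
using namespace Rcpp;
using hm::Vec3;

// Selective red/green refinement enforcing a triangle circumradius bound.
// Triangles above the bound are quartered at edge midpoints; neighbors with
// hanging midpoints are bisected (1 split edge -> 2 triangles, 2 -> 3).
// Midpoints are welded globally, so the surface stays closed and conformal.

namespace {
double circumradius(const Vec3& a, const Vec3& b, const Vec3& c) {
  double la = hm::norm(b - c), lb = hm::norm(a - c), lc = hm::norm(a - b);
  Vec3 n = hm::cross(b - a, c - a);
  double K = hm::norm(n) / 2.0;
  if (K < 1e-300) return std::numeric_limits<double>::infinity();
  return la * lb * lc / (4.0 * K);
}
}  // namespace

// [[Rcpp::export]]
List cpp_refine_circumradius(NumericMatrix Vin, IntegerMatrix Fin, double rmax,
                             int max_rounds) {
  std::vector<Vec3> P;
  P.reserve(Vin.nrow());
  for (int i = 0; i < Vin.nrow(); ++i)
    P.emplace_back(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<std::array<int, 3>> F(Fin.nrow());
  for (int t = 0; t < Fin.nrow(); ++t) F[t] = {Fin(t, 0), Fin(t, 1), Fin(t, 2)};

  for (int round = 0; round < max_rounds; ++round) {
    std::vector<char> red(F.size(), 0);
    size_t nred = 0;
    for (size_t t = 0; t < F.size(); ++t) {
      const Vec3 &a = P[F[t][0]], &b = P[F[t][1]], &c = P[F[t][2]];
      // near-degenerate triangles have an unbounded circumradius that no
      // amount of midpoint subdivision will cure; leave them alone
      if (hm::norm(hm::cross(b - a, c - a)) < 1e-10) continue;
      if (circumradius(a, b, c) > rmax) {
        red[t] = 1;
        ++nred;
      }
    }
    if (nred == 0) break;
    std::unordered_map<uint64_t, int> mid;
    auto midpoint = [&](int a, int b) {
      uint64_t k = hm::edge_key(a, b);
      auto it = mid.find(k);
      if (it != mid.end()) return it->second;
      int id = (int)P.size();
      P.push_back((P[a] + P[b]) * 0.5);
      mid.emplace(k, id);
      return id;
    };
    // register midpoints of red triangles
    for (size_t t = 0; t < F.size(); ++t)
      if (red[t]) {
        midpoint(F[t][0], F[t][1]);
        midpoint(F[t][1], F[t][2]);
        midpoint(F[t][2], F[t][0]);
      }
    std::vector<std::array<int, 3>> out;
    out.reserve(F.size() + 4 * nred);
    for (size_t t = 0; t < F.size(); ++t) {
      int a = F[t][0], b = F[t][1], c = F[t][2];
      int mab = -1, mbc = -1, mca = -1, nsplit = 0;
      auto look = [&](int x, int y) {
        auto it = mid.find(hm::edge_key(x, y));
        return it == mid.end() ? -1 : it->second;
      };
      mab = look(a, b); mbc = look(b, c); mca = look(c, a);
      nsplit = (mab >= 0) + (mbc >= 0) + (mca >= 0);
      if (nsplit == 0) {
        out.push_back({a, b, c});
      } else if (nsplit == 3) {
        out.push_back({a, mab, mca});
        out.push_back({mab, b, mbc});
        out.push_back({mca, mbc, c});
        out.push_back({mab, mbc, mca});
      } else if (nsplit == 1) {
        if (mab >= 0) { out.push_back({a, mab, c}); out.push_back({mab, b, c}); }
        else if (mbc >= 0) { out.push_back({b, mbc, a}); out.push_back({mbc, c, a}); }
        else { out.push_back({c, mca, b}); out.push_back({mca, a, b}); }
      } else {
        // two split edges: rotate so the unsplit edge is (a,b)
        int ra = a, rb = b, rc = c, m1, m2;
        if (mab < 0) { m1 = mbc; m2 = mca; }            // edges (b,c), (c,a)
        else if (mbc < 0) { ra = b; rb = c; rc = a; m1 = mca; m2 = mab; }
        else { ra = c; rb = a; rc = b; m1 = mab; m2 = mbc; }
        // m1 on (rb,rc), m2 on (rc,ra)
        out.push_back({m2, m1, rc});
        // split quad (ra, rb, m1, m2) by the shorter diagonal for shape
        double d1 = hm::dist2(P[ra], P[m1]), d2 = hm::dist2(P[rb], P[m2]);
        if (d1 <= d2) {
          out.push_back({ra, rb, m1});
          out.push_back({ra, m1, m2});
        } else {
          out.push_back({ra, rb, m2});
          out.push_back({rb, m1, m2});
        }
      }
    }
    F.swap(out);
  }

  NumericMatrix V2((int)P.size(), 3);
  for (size_t i = 0; i < P.size(); ++i) {
    V2(i, 0) = P[i].x; V2(i, 1) = P[i].y; V2(i, 2) = P[i].z;
  }
  IntegerMatrix F2((int)F.size(), 3);
  for (size_t t = 0; t < F.size(); ++t) {
    F2(t, 0) = F[t][0]; F2(t, 1) = F[t][1]; F2(t, 2) = F[t][2];
  }
  return List::create(_["vertices"] = V2, _["faces"] = F2);
}
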