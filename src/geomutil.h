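#ifndef HEADMESHER_GEOMUTIL_H
#define HEADMESHER_GEOMUTIL_H

#include <cmath>
#include <cstdint>
#include <array>
#include <vector>
#include <limits>

namespace hm {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};

inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline double dist2(const Vec3& a, const Vec3& b) {
  Vec3 d = a - b;
  return dot(d, d);
}

// signed volume of tetrahedron (a,b,c,d)
inline double tet_signed_volume(const Vec3& a, const Vec3& b, const Vec3& c, const Vec3& d) {
  return dot(b - a, cross(c - a, d - a)) / 6.0;
}

// closest point on triangle (a,b,c) to p  (Ericson, Real-Time Collision Detection)
inline Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// Moller-Trumbore; returns true on hit with t > 0.  `robust` is set false when the
// hit is too close to the triangle boundary or the ray is near-parallel, in which
// case the caller should retry with a perturbed ray.
inline bool ray_triangle(const Vec3& orig, const Vec3& dir,
                         const Vec3& v0, const Vec3& v1, const Vec3& v2,
                         double& t, bool& robust) {
  const double EPS_DET = 1e-14, EPS_BARY = 1e-10;
  Vec3 e1 = v1 - v0, e2 = v2 - v0;
  Vec3 pvec = cross(dir, e2);
  double det = dot(e1, pvec);
  if (std::fabs(det) < EPS_DET) {
    // ray parallel to the triangle plane: a clean miss unless the ray lies
    // in the plane itself, which perturbation must resolve
    Vec3 n = cross(e1, e2);
    double nn = norm(n);
    if (nn > 0 && std::fabs(dot(n, orig - v0)) / nn < 1e-9) robust = false;
    return false;
  }
  double inv = 1.0 / det;
  Vec3 tvec = orig - v0;
  double u = dot(tvec, pvec) * inv;
  if (u < -EPS_BARY || u > 1.0 + EPS_BARY) return false;
  Vec3 qvec = cross(tvec, e1);
  double v = dot(dir, qvec) * inv;
  if (v < -EPS_BARY || u + v > 1.0 + EPS_BARY) return false;
  t = dot(e2, qvec) * inv;
  if (u < EPS_BARY || v < EPS_BARY || u + v > 1.0 - EPS_BARY || std::fabs(t) < 1e-12)
    robust = false;
  return t > 0.0;
}

inline uint64_t edge_key(uint64_t a, uint64_t b) {
  return a < b ? (a << 32) | b : (b << 32) | a;
}

}  // namespace hm

#endif
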