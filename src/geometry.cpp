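// Point-mesh distance and containment queries.
//
// Distances are exact closest-point computations (Ericson's barycentric
// region classification).  The "accelerated" mesh query prunes faces by a
// lower bound from per-face axis-aligned bounding boxes and is required by
// contract to return results identical to the exhaustive scan.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
};
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

// Closest point on triangle (a,b,c) to p.  Ericson, Real-Time Collision
// Detection, 5.1.5.
static V3 closest_point_triangle(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) { double v = d1 / (d1 - d3); return a + v * ab; }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) { double w = d2 / (d2 - d6); return a + w * ac; }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

// [[Rcpp::export]]
List cpp_point_triangle_distance(NumericVector p, NumericVector a,
                                 NumericVector b, NumericVector c) {
  V3 cp = closest_point_triangle(V3(p[0], p[1], p[2]), V3(a[0], a[1], a[2]),
                                 V3(b[0], b[1], b[2]), V3(c[0], c[1], c[2]));
  V3 d = V3(p[0], p[1], p[2]) - cp;
  return List::create(_["distance"] = std::sqrt(dot(d, d)),
                      _["closest_point"] = NumericVector::create(cp.x, cp.y, cp.z));
}

static inline double aabb_lower_bound(const V3& p, const double* lo, const double* hi) {
  double dx = std::max(std::max(lo[0] - p.x, 0.0), p.x - hi[0]);
  double dy = std::max(std::max(lo[1] - p.y, 0.0), p.y - hi[1]);
  double dz = std::max(std::max(lo[2] - p.z, 0.0), p.z - hi[2]);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Batch point-to-mesh distance.  P: n x 3 query points; V: vertices; F:
// zero-based faces.  Returns distance, 1-based face index and closest point
// per query.  accel=true enables AABB pruning (identical results).
// [[Rcpp::export]]
List cpp_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                       bool accel) {
  int n = P.nrow(), m = F.nrow();
  if (m == 0) stop("mesh_distance: empty mesh");
  std::vector<V3> va(m), vb(m), vc(m);
  std::vector<double> lo(3 * m), hi(3 * m);
  for (int j = 0; j < m; ++j) {
    int i0 = F(j, 0), i1 = F(j, 1), i2 = F(j, 2);
    va[j] = V3(V(i0, 0), V(i0, 1), V(i0, 2));
    vb[j] = V3(V(i1, 0), V(i1, 1), V(i1, 2));
    vc[j] = V3(V(i2, 0), V(i2, 1), V(i2, 2));
    lo[3 * j] = std::min(va[j].x, std::min(vb[j].x, vc[j].x));
    lo[3 * j + 1] = std::min(va[j].y, std::min(vb[j].y, vc[j].y));
    lo[3 * j + 2] = std::min(va[j].z, std::min(vb[j].z, vc[j].z));
    hi[3 * j] = std::max(va[j].x, std::max(vb[j].x, vc[j].x));
    hi[3 * j + 1] = std::max(va[j].y, std::max(vb[j].y, vc[j].y));
    hi[3 * j + 2] = std::max(va[j].z, std::max(vb[j].z, vc[j].z));
  }
  NumericVector dist(n);
  IntegerVector face(n);
  NumericMatrix cp(n, 3);
  for (int i = 0; i < n; ++i) {
    V3 p(P(i, 0), P(i, 1), P(i, 2));
    double best = std::numeric_limits<double>::infinity();
    int bestj = -1;
    V3 bestcp;
    for (int j = 0; j < m; ++j) {
      if (accel && aabb_lower_bound(p, &lo[3 * j], &hi[3 * j]) >= best) continue;
      V3 q = closest_point_triangle(p, va[j], vb[j], vc[j]);
      V3 d = p - q;
      double dd = std::sqrt(dot(d, d));
      if (dd < best) { best = dd; bestj = j; bestcp = q; }
    }
    dist[i] = best;
    face[i] = bestj + 1;
    cp(i, 0) = bestcp.x; cp(i, 1) = bestcp.y; cp(i, 2) = bestcp.z;
  }
  return List::create(_["distance"] = dist, _["face"] = face,
                      _["closest_point"] = cp);
}

// Ray-crossing parity containment test for watertight meshes.  For each
// query point, a ray is cast along a fixed direction; intersections too
// close to a triangle edge/vertex trigger a retry with the next direction
// in a fixed, deterministic list.
// [[Rcpp::export]]
LogicalVector cpp_point_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow(), m = F.nrow();
  const double EPS = 1e-10, BARY_EPS = 1e-9;
  // deterministic retry directions (unnormalized is fine)
  const double dirs[8][3] = {
    {1.0, 0.017, 0.031}, {0.013, 1.0, 0.023}, {0.029, 0.011, 1.0},
    {1.0, 0.513, 0.331}, {-1.0, 0.217, 0.113}, {0.413, -1.0, 0.271},
    {0.157, 0.367, -1.0}, {1.0, -0.713, 0.431}};
  // global AABB quick reject: a point strictly outside the bounding box of
  // all vertices cannot be inside the mesh (exact, no approximation)
  double blo[3], bhi[3];
  for (int k = 0; k < 3; ++k) { blo[k] = R_PosInf; bhi[k] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      blo[k] = std::min(blo[k], V(i, k));
      bhi[k] = std::max(bhi[k], V(i, k));
    }
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    V3 o(P(i, 0), P(i, 1), P(i, 2));
    if (o.x < blo[0] || o.x > bhi[0] || o.y < blo[1] || o.y > bhi[1] ||
        o.z < blo[2] || o.z > bhi[2]) {
      inside[i] = false;
      continue;
    }
    bool done = false;
    for (int attempt = 0; attempt < 8 && !done; ++attempt) {
      V3 d(dirs[attempt][0], dirs[attempt][1], dirs[attempt][2]);
      int crossings = 0;
      bool degenerate = false;
      for (int j = 0; j < m && !degenerate; ++j) {
        int i0 = F(j, 0), i1 = F(j, 1), i2 = F(j, 2);
        V3 a(V(i0, 0), V(i0, 1), V(i0, 2));
        V3 b(V(i1, 0), V(i1, 1), V(i1, 2));
        V3 c(V(i2, 0), V(i2, 1), V(i2, 2));
        // Moeller-Trumbore
        V3 e1 = b - a, e2 = c - a;
        V3 pv = cross(d, e2);
        double det = dot(e1, pv);
        if (std::fabs(det) < EPS) continue;  // parallel
        double inv = 1.0 / det;
        V3 tv = o - a;
        double u = dot(tv, pv) * inv;
        V3 qv = cross(tv, e1);
        double v = dot(d, qv) * inv;
        double t = dot(e2, qv) * inv;
        if (t <= EPS) continue;              // behind or on the origin
        if (u < -BARY_EPS || v < -BARY_EPS || u + v > 1 + BARY_EPS) continue;
        if (u < BARY_EPS || v < BARY_EPS || u + v > 1 - BARY_EPS) {
          degenerate = true;                 // edge/vertex graze: retry
          continue;
        }
        ++crossings;
      }
      if (!degenerate) { inside[i] = (crossings % 2) == 1; done = true; }
    }
    if (!done) inside[i] = NA_LOGICAL;       // pathological; never expected
  }
  return inside;
}
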