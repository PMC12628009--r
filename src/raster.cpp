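// Deterministic software z-buffer rasterizer for label/depth maps.
//
// Image convention: origin top-left, u right, v down, pixel centres at
// integer coordinates; a pixel is covered when its centre lies inside the
// projected triangle, ties resolved by a top-left fill rule.  Lens
// distortion is applied to (subdivided) vertices, not per pixel: triangles
// whose undistorted projected edges exceed `edge_subdiv` pixels are
// recursively split at 3D edge midpoints before distortion, bounding the
// straight-edge error distortion would otherwise introduce.
//
// Depth is camera +Z in mm, perspective-correct (1/z interpolated over
// screen barycentrics); 0 encodes "empty".

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cam {
  double fx, fy, cx, cy, k1, k2, p1, p2, k3;
  int width, height;
};

struct SV { double u, v, z; };  // screen vertex

// distorted pinhole projection of a camera-frame point (z > 0 assumed)
static inline SV project_distorted(const Cam& c, double x, double y, double z) {
  double xn = x / z, yn = y / z;
  double r2 = xn * xn + yn * yn;
  double rad = 1.0 + r2 * (c.k1 + r2 * (c.k2 + r2 * c.k3));
  double xd = xn * rad + 2.0 * c.p1 * xn * yn + c.p2 * (r2 + 2.0 * xn * xn);
  double yd = yn * rad + c.p1 * (r2 + 2.0 * yn * yn) + 2.0 * c.p2 * xn * yn;
  SV s; s.u = c.fx * xd + c.cx; s.v = c.fy * yd + c.cy; s.z = z;
  return s;
}

static inline double edge_fn(const SV& a, const SV& b, double pu, double pv) {
  return (b.u - a.u) * (pv - a.v) - (b.v - a.v) * (pu - a.u);
}

// top-left rule for CCW winding (u right, v down): an edge with direction
// (du, dv) is "top" when dv == 0 && du > 0, "left" when dv < 0.
static inline bool top_left(const SV& a, const SV& b) {
  double du = b.u - a.u, dv = b.v - a.v;
  return (dv == 0.0 && du > 0.0) || dv < 0.0;
}

struct Raster {
  Cam cam;
  int label;
  double edge_subdiv;
  int* labelbuf;   // height x width, column-major (R matrix)
  double* zbuf;
  int H, W;

  void fill(SV a, SV b, SV c) {
    double area = edge_fn(a, b, c.u, c.v);
    if (area == 0.0) return;
    if (area < 0.0) { SV t = b; b = c; c = t; area = -area; }
    int u0 = (int)std::ceil(std::min(a.u, std::min(b.u, c.u)));
    int u1 = (int)std::floor(std::max(a.u, std::max(b.u, c.u)));
    int v0 = (int)std::ceil(std::min(a.v, std::min(b.v, c.v)));
    int v1 = (int)std::floor(std::max(a.v, std::max(b.v, c.v)));
    if (u0 < 0) u0 = 0;
    if (v0 < 0) v0 = 0;
    if (u1 > W - 1) u1 = W - 1;
    if (v1 > H - 1) v1 = H - 1;
    if (u0 > u1 || v0 > v1) return;
    bool tl0 = top_left(b, c), tl1 = top_left(c, a), tl2 = top_left(a, b);
    double iza = 1.0 / a.z, izb = 1.0 / b.z, izc = 1.0 / c.z;
    for (int v = v0; v <= v1; ++v) {
      for (int u = u0; u <= u1; ++u) {
        double w0 = edge_fn(b, c, (double)u, (double)v);
        double w1 = edge_fn(c, a, (double)u, (double)v);
        double w2 = edge_fn(a, b, (double)u, (double)v);
        bool in = (w0 > 0.0 || (w0 == 0.0 && tl0)) &&
                  (w1 > 0.0 || (w1 == 0.0 && tl1)) &&
                  (w2 > 0.0 || (w2 == 0.0 && tl2));
        if (!in) continue;
        double iz = (w0 * iza + w1 * izb + w2 * izc) / area;
        double z = 1.0 / iz;
        double* zp = &zbuf[(size_t)u * H + v];
        if (*zp == 0.0 || z < *zp) {
          *zp = z;
          labelbuf[(size_t)u * H + v] = label;
        }
      }
    }
  }

  // recursive subdivision on undistorted projected edge length
  void tri(const double* pa, const double* pb, const double* pc, int depth) {
    double ua = cam.fx * pa[0] / pa[2] + cam.cx, va = cam.fy * pa[1] / pa[2] + cam.cy;
    double ub = cam.fx * pb[0] / pb[2] + cam.cx, vb = cam.fy * pb[1] / pb[2] + cam.cy;
    double uc = cam.fx * pc[0] / pc[2] + cam.cx, vc = cam.fy * pc[1] / pc[2] + cam.cy;
    double e0 = std::hypot(ub - ua, vb - va);
    double e1 = std::hypot(uc - ub, vc - vb);
    double e2 = std::hypot(ua - uc, va - vc);
    double emax = std::max(e0, std::max(e1, e2));
    if (emax > edge_subdiv && depth < 24) {
      // bisect the longest projected edge (anisotropic: long thin
      // triangles split only lengthwise)
      const double *qa = pa, *qb = pb, *qc = pc;
      if (e1 >= e0 && e1 >= e2) { qa = pb; qb = pc; qc = pa; }
      else if (e2 >= e0 && e2 >= e1) { qa = pc; qb = pa; qc = pb; }
      double m[3];
      for (int k = 0; k < 3; ++k) m[k] = 0.5 * (qa[k] + qb[k]);
      tri(qa, m, qc, depth + 1);
      tri(m, qb, qc, depth + 1);
      return;
    }
    fill(project_distorted(cam, pa[0], pa[1], pa[2]),
         project_distorted(cam, pb[0], pb[1], pb[2]),
         project_distorted(cam, pc[0], pc[1], pc[2]));
  }
};

}  // namespace

// Rasterize one mesh (vertices already in the camera optical frame, mm)
// into label/depth buffers, which are modified in place.  F is zero-based.
// Triangles with any vertex at z < z_near are clipped (dropped).
// [[Rcpp::export]]
void cpp_render_mesh(NumericMatrix V, IntegerMatrix F, int label,
                     NumericVector cam, int width, int height,
                     double z_near, double edge_subdiv,
                     IntegerMatrix labelbuf, NumericMatrix zbuf) {
  if (labelbuf.nrow() != height || labelbuf.ncol() != width ||
      zbuf.nrow() != height || zbuf.ncol() != width)
    stop("render: buffer dimensions mismatch");
  Raster r;
  r.cam.fx = cam[0]; r.cam.fy = cam[1]; r.cam.cx = cam[2]; r.cam.cy = cam[3];
  r.cam.k1 = cam[4]; r.cam.k2 = cam[5]; r.cam.p1 = cam[6]; r.cam.p2 = cam[7];
  r.cam.k3 = cam[8];
  r.cam.width = width; r.cam.height = height;
  r.label = label;
  r.edge_subdiv = edge_subdiv;
  r.labelbuf = labelbuf.begin();
  r.zbuf = zbuf.begin();
  r.H = height; r.W = width;
  int m = F.nrow();
  for (int j = 0; j < m; ++j) {
    int i0 = F(j, 0), i1 = F(j, 1), i2 = F(j, 2);
    double pa[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
    double pb[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
    double pc[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
    if (pa[2] < z_near || pb[2] < z_near || pc[2] < z_near) continue;
    r.tri(pa, pb, pc, 0);
  }
}
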