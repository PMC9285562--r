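// Unsigned point-to-mesh distances: for each query point, the exact
// distance to the nearest point on any reference triangle.  Triangles are
// bucketed into a uniform grid by their bounding boxes and queries search
// expanding Chebyshev shells with a conservative lower-bound cutoff.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline double dot(const V3& a, const V3& b) {
  return a.x*b.x + a.y*b.y + a.z*b.z;
}

// closest-point-on-triangle (Ericson, Real-Time Collision Detection)
double pointTriDist2(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { V3 d = sub(p, a); return dot(d, d); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { V3 d = sub(p, b); return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    V3 q = {a.x + v*ab.x, a.y + v*ab.y, a.z + v*ab.z};
    V3 d = sub(p, q); return dot(d, d);
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { V3 d = sub(p, c); return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    V3 q = {a.x + w*ac.x, a.y + w*ac.y, a.z + w*ac.z};
    V3 d = sub(p, q); return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = {b.x + w*(c.x-b.x), b.y + w*(c.y-b.y), b.z + w*(c.z-b.z)};
    V3 d = sub(p, q); return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = {a.x + ab.x*v + ac.x*w, a.y + ab.y*v + ac.y*w,
          a.z + ab.z*v + ac.z*w};
  V3 d = sub(p, q); return dot(d, d);
}

}  // namespace

// [[Rcpp::export(name = ".pointMeshDistances")]]
NumericVector pointMeshDistances(NumericMatrix points, NumericMatrix verts,
                                 IntegerMatrix tris) {
  int np = points.nrow(), nt = tris.nrow();
  NumericVector out(np);
  if (nt == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }

  // bounding box of reference mesh
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  int nv = verts.nrow();
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], verts(i, k));
      hi[k] = std::max(hi[k], verts(i, k));
    }
  double ext[3];
  for (int k = 0; k < 3; ++k) ext[k] = std::max(hi[k] - lo[k], 1e-12);
  double cs = std::cbrt(ext[0] * ext[1] * ext[2] / std::max(nt, 1)) * 2.0;
  cs = std::max(cs, 1e-9);
  int ng[3];
  for (int k = 0; k < 3; ++k)
    ng[k] = std::max(1, std::min(256, (int)std::ceil(ext[k] / cs)));
  double csk[3];
  for (int k = 0; k < 3; ++k) csk[k] = ext[k] / ng[k];

  auto cellOf = [&](double x, int k) {
    int c = (int)std::floor((x - lo[k]) / csk[k]);
    return std::max(0, std::min(ng[k] - 1, c));
  };
  int ncell = ng[0] * ng[1] * ng[2];
  std::vector<std::vector<int>> buckets(ncell);
  for (int t = 0; t < nt; ++t) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int m = 0; m < 3; ++m) {
      int v = tris(t, m) - 1;
      for (int k = 0; k < 3; ++k) {
        tlo[k] = std::min(tlo[k], verts(v, k));
        thi[k] = std::max(thi[k], verts(v, k));
      }
    }
    int c0[3], c1[3];
    for (int k = 0; k < 3; ++k) {
      c0[k] = cellOf(tlo[k], k); c1[k] = cellOf(thi[k], k);
    }
    for (int kz = c0[2]; kz <= c1[2]; ++kz)
      for (int ky = c0[1]; ky <= c1[1]; ++ky)
        for (int kx = c0[0]; kx <= c1[0]; ++kx)
          buckets[kx + ng[0] * (ky + ng[1] * kz)].push_back(t);
  }

  double minCs = std::min({csk[0], csk[1], csk[2]});
  int maxR = ng[0] + ng[1] + ng[2];
  for (int ip = 0; ip < np; ++ip) {
    V3 p = {points(ip, 0), points(ip, 1), points(ip, 2)};
    int pc[3] = {cellOf(p.x, 0), cellOf(p.y, 1), cellOf(p.z, 2)};
    double best2 = R_PosInf;
    for (int r = 0; r <= maxR; ++r) {
      // conservative lower bound on distance to any cell in shell r
      double lb = (r - 1) * minCs;
      if (r > 1 && lb * lb > best2) break;
      bool any = false;
      int x0 = std::max(0, pc[0] - r), x1 = std::min(ng[0] - 1, pc[0] + r);
      int y0 = std::max(0, pc[1] - r), y1 = std::min(ng[1] - 1, pc[1] + r);
      int z0 = std::max(0, pc[2] - r), z1 = std::min(ng[2] - 1, pc[2] + r);
      for (int kz = z0; kz <= z1; ++kz)
        for (int ky = y0; ky <= y1; ++ky)
          for (int kx = x0; kx <= x1; ++kx) {
            int cheb = std::max({std::abs(kx - pc[0]), std::abs(ky - pc[1]),
                                 std::abs(kz - pc[2])});
            if (cheb != r) continue;  // only the shell
            any = true;
            const std::vector<int>& bucket =
              buckets[kx + ng[0] * (ky + ng[1] * kz)];
            for (int t : bucket) {
              const int v0 = tris(t, 0) - 1, v1 = tris(t, 1) - 1,
                        v2 = tris(t, 2) - 1;
              V3 a = {verts(v0, 0), verts(v0, 1), verts(v0, 2)};
              V3 b = {verts(v1, 0), verts(v1, 1), verts(v1, 2)};
              V3 c = {verts(v2, 0), verts(v2, 1), verts(v2, 2)};
              double d2 = pointTriDist2(p, a, b, c);
              if (d2 < best2) best2 = d2;
            }
          }
      if (!any && r > maxR) break;
    }
    out[ip] = std::sqrt(best2);
  }
  return out;
}
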