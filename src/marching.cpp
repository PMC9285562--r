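// Iso-surface extraction by marching tetrahedra: each grid cube is split
// into the six Kuhn tetrahedra sharing the main diagonal, and the iso = c
// level set of the linear interpolant on each tetrahedron is triangulated.
// Vertices on shared grid edges are deduplicated, so the output mesh is
// watertight wherever the level set is closed.  Triangles are wound so
// that normals point away from the enclosed (field >= iso) region.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// the six tetrahedra of the Kuhn subdivision; corner ids are bit codes
// (bit0 = +x, bit1 = +y, bit2 = +z) of the cube corners
const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

struct MeshBuilder {
  std::unordered_map<uint64_t, int> edgeVertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const double* f;
  double iso;
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;

  inline uint64_t gid(int i, int j, int k) const {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  }
  inline double fval(uint64_t g) const { return f[g]; }
  inline Vec3 gpos(uint64_t g) const {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((uint64_t)nx * ny));
    return {ox + sx * i, oy + sy * j, oz + sz * k};
  }

  // interpolated vertex on grid edge (g1, g2); one endpoint inside,
  // the other outside, so f1 != f2
  int edgePoint(uint64_t g1, uint64_t g2) {
    if (g1 > g2) std::swap(g1, g2);
    uint64_t key = g1 * 0x100000001ULL ^ g2;  // not unique; use map of pairs
    (void)key;
    uint64_t pk = (g1 << 32) | (g2 & 0xffffffffULL);
    auto it = edgeVertex.find(pk);
    if (it != edgeVertex.end()) return it->second;
    double f1 = fval(g1), f2 = fval(g2);
    double t = (iso - f1) / (f2 - f1);
    if (t < 0) t = 0; if (t > 1) t = 1;
    Vec3 p1 = gpos(g1), p2 = gpos(g2);
    vx.push_back(p1.x + t * (p2.x - p1.x));
    vy.push_back(p1.y + t * (p2.y - p1.y));
    vz.push_back(p1.z + t * (p2.z - p1.z));
    int id = (int)vx.size() - 1;
    edgeVertex.emplace(pk, id);
    return id;
  }

  inline Vec3 vpos(int id) const { return {vx[id], vy[id], vz[id]}; }

  // append triangle (a,b,c), flipping so the normal points from the inside
  // centroid towards the outside
  void addTri(int a, int b, int c, const Vec3& insideRef) {
    Vec3 pa = vpos(a), pb = vpos(b), pc = vpos(c);
    Vec3 n = cross(sub(pb, pa), sub(pc, pa));
    Vec3 centroid = {(pa.x + pb.x + pc.x) / 3.0, (pa.y + pb.y + pc.y) / 3.0,
                     (pa.z + pb.z + pc.z) / 3.0};
    if (dot(n, sub(centroid, insideRef)) < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }

  void doTet(const uint64_t g[4]) {
    bool in[4];
    int nin = 0;
    for (int m = 0; m < 4; ++m) { in[m] = fval(g[m]) >= iso; nin += in[m]; }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4]; int ni = 0, no = 0;
    for (int m = 0; m < 4; ++m) (in[m] ? ins[ni++] : outs[no++]) = m;
    if (nin == 1 || nin == 3) {
      int apex = (nin == 1) ? ins[0] : outs[0];
      const int* others = (nin == 1) ? outs : ins;
      int e0 = edgePoint(g[apex], g[others[0]]);
      int e1 = edgePoint(g[apex], g[others[1]]);
      int e2 = edgePoint(g[apex], g[others[2]]);
      Vec3 ref;
      if (nin == 1) ref = gpos(g[apex]);
      else {
        Vec3 p0 = gpos(g[ins[0]]), p1 = gpos(g[ins[1]]), p2 = gpos(g[ins[2]]);
        ref = {(p0.x + p1.x + p2.x) / 3.0, (p0.y + p1.y + p2.y) / 3.0,
               (p0.z + p1.z + p2.z) / 3.0};
      }
      addTri(e0, e1, e2, ref);
    } else {
      // two in, two out: quad split into two triangles
      int e00 = edgePoint(g[ins[0]], g[outs[0]]);
      int e01 = edgePoint(g[ins[0]], g[outs[1]]);
      int e10 = edgePoint(g[ins[1]], g[outs[0]]);
      int e11 = edgePoint(g[ins[1]], g[outs[1]]);
      Vec3 p0 = gpos(g[ins[0]]), p1 = gpos(g[ins[1]]);
      Vec3 ref = {(p0.x + p1.x) / 2.0, (p0.y + p1.y) / 2.0,
                  (p0.z + p1.z) / 2.0};
      addTri(e00, e01, e11, ref);
      addTri(e00, e11, e10, ref);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".marchingTetrahedra")]]
List marchingTetrahedra(NumericVector field, IntegerVector dims, double iso,
                        NumericVector spacing, NumericVector origin) {
  MeshBuilder mb;
  mb.f = REAL(field);
  mb.iso = iso;
  mb.nx = dims[0]; mb.ny = dims[1]; mb.nz = dims[2];
  mb.sx = spacing[0]; mb.sy = spacing[1]; mb.sz = spacing[2];
  mb.ox = origin[0]; mb.oy = origin[1]; mb.oz = origin[2];

  for (int k = 0; k + 1 < mb.nz; ++k)
    for (int j = 0; j + 1 < mb.ny; ++j)
      for (int i = 0; i + 1 < mb.nx; ++i) {
        uint64_t corner[8];
        for (int c = 0; c < 8; ++c)
          corner[c] = mb.gid(i + (c & 1), j + ((c >> 1) & 1),
                             k + ((c >> 2) & 1));
        // skip cubes with all corners on one side
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          if (mb.fval(corner[c]) >= iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t g[4];
          for (int m = 0; m < 4; ++m) g[m] = corner[TETS[t][m]];
          mb.doTet(g);
        }
      }

  int nv = (int)mb.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = mb.vx[i]; verts(i, 1) = mb.vy[i]; verts(i, 2) = mb.vz[i];
  }
  int nt = (int)mb.tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int i = 0; i < nt; ++i) {
    tris(i, 0) = mb.tri[3 * i] + 1;
    tris(i, 1) = mb.tri[3 * i + 1] + 1;
    tris(i, 2) = mb.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// connected components over shared vertices; returns 1-based component id
// per vertex (0 for unreferenced vertices)
// [[Rcpp::export(name = ".meshComponents")]]
IntegerVector meshComponents(IntegerMatrix tris, int nvert) {
  std::vector<int> parent(nvert + 1);
  for (int i = 0; i <= nvert; ++i) parent[i] = i;
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  int nt = tris.nrow();
  for (int t = 0; t < nt; ++t) {
    unite(tris(t, 0), tris(t, 1));
    unite(tris(t, 1), tris(t, 2));
  }
  std::unordered_map<int, int> relabel;
  IntegerVector comp(nvert);
  for (int v = 1; v <= nvert; ++v) {
    int r = find(v);
    auto it = relabel.find(r);
    int id;
    if (it == relabel.end()) {
      id = (int)relabel.size() + 1;
      relabel.emplace(r, id);
    } else id = it->second;
    comp[v - 1] = id;
  }
  return comp;
}
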