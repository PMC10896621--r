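// Iso-surface extraction by marching tetrahedra on a regular grid.
// The cube is split into the six Kuhn tetrahedra sharing the main diagonal;
// this subdivision is conforming across neighbouring cubes, and every
// iso-vertex lies on a grid edge keyed by its two grid-node ids, so the
// extracted surface is watertight by construction (away from the grid
// boundary, which callers pad).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;
};

inline double field_val(const double* f, size_t idx) {
  double v = f[idx];
  if (v == 0.0) v = 1e-12;  // nudge exact zeros so signs are well defined
  return v;
}

}  // namespace

// [[Rcpp::export(name = ".mtet_extract")]]
List mtet_extract(NumericVector field, IntegerVector dims,
                  NumericVector origin, double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != field.size())
    stop("field length does not match grid dimensions");
  const double* f = REAL(field);
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // Kuhn subdivision: six vertex orders from corner 0 to corner 7.
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  MeshAcc acc;
  const uint64_t nnode = (uint64_t)nx * ny * nz;

  auto node_coord = [&](uint64_t gid, double* p) {
    uint64_t i = gid % nx, j = (gid / nx) % ny, k = gid / ((uint64_t)nx * ny);
    p[0] = ox + spacing * i;
    p[1] = oy + spacing * j;
    p[2] = oz + spacing * k;
  };

  auto edge_point = [&](uint64_t ga, uint64_t gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    uint64_t key = ga * nnode + gb;
    auto it = acc.edge_vertex.find(key);
    if (it != acc.edge_vertex.end()) return it->second;
    double fa = field_val(f, ga), fb = field_val(f, gb);
    double t = fa / (fa - fb);
    if (t < 0) t = 0; else if (t > 1) t = 1;
    double pa[3], pb[3];
    node_coord(ga, pa);
    node_coord(gb, pb);
    acc.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    acc.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    acc.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)acc.vx.size() - 1;
    acc.edge_vertex.emplace(key, id);
    return id;
  };

  auto add_tri = [&](int a, int b, int c, bool flip) {
    if (flip) std::swap(b, c);
    acc.f0.push_back(a);
    acc.f1.push_back(b);
    acc.f2.push_back(c);
  };

  // parity of a permutation of {0,1,2,3}
  auto perm_sign = [](const int p[4]) {
    int inv = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i + 1; j < 4; ++j)
        if (p[i] > p[j]) ++inv;
    return (inv % 2 == 0) ? 1 : -1;
  };

  // geometric orientation sign of each Kuhn tetrahedron (precomputed)
  static const int tet_sign[6] = {+1, -1, -1, +1, +1, -1};

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        uint64_t base = (uint64_t)i + (uint64_t)nx * (j + (uint64_t)ny * k);
        uint64_t corner[8];
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          corner[c] = base + di + (uint64_t)nx * (dj + (uint64_t)ny * dk);
        }
        // quick reject: all same sign
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          if (field_val(f, corner[c]) < 0) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          uint64_t g[4];
          double fv[4];
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v) {
            g[v] = corner[tets[t][v]];
            fv[v] = field_val(f, g[v]);
            if (fv[v] < 0) in_idx[nin++] = v; else out_idx[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;

          // canonical winding: sign = tet orientation x permutation parity
          // (inside vertices listed first); negative sign flips the winding
          int perm[4];
          for (int v = 0; v < nin; ++v) perm[v] = in_idx[v];
          for (int v = 0; v < nout; ++v) perm[nin + v] = out_idx[v];
          bool flip;

          if (nin == 1) {
            flip = tet_sign[t] * perm_sign(perm) < 0;
            int a = in_idx[0];
            add_tri(edge_point(g[a], g[out_idx[0]]),
                    edge_point(g[a], g[out_idx[1]]),
                    edge_point(g[a], g[out_idx[2]]), flip);
          } else if (nin == 3) {
            // list the outside vertex first, then invert the reference
            // winding (reference rule is built for one-inside-first)
            int perm2[4] = {out_idx[0], in_idx[0], in_idx[1], in_idx[2]};
            flip = tet_sign[t] * perm_sign(perm2) > 0;
            int a = out_idx[0];
            add_tri(edge_point(g[a], g[in_idx[0]]),
                    edge_point(g[a], g[in_idx[1]]),
                    edge_point(g[a], g[in_idx[2]]), flip);
          } else {  // nin == 2: quad (i1-o1, i1-o2, i2-o2, i2-o1)
            flip = tet_sign[t] * perm_sign(perm) < 0;
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            int p0 = edge_point(g[a], g[c]);
            int p1 = edge_point(g[a], g[d]);
            int p2 = edge_point(g[b], g[d]);
            int p3 = edge_point(g[b], g[c]);
            if (flip) {
              add_tri(p0, p3, p2, false);
              add_tri(p0, p2, p1, false);
            } else {
              add_tri(p0, p1, p2, false);
              add_tri(p0, p2, p3, false);
            }
          }
        }
      }
    }
  }

  size_t nv = acc.vx.size(), nf = acc.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (size_t v = 0; v < nv; ++v) {
    V(v, 0) = acc.vx[v];
    V(v, 1) = acc.vy[v];
    V(v, 2) = acc.vz[v];
  }
  for (size_t t = 0; t < nf; ++t) {
    F(t, 0) = acc.f0[t] + 1;
    F(t, 1) = acc.f1[t] + 1;
    F(t, 2) = acc.f2[t] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
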