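// Ray casting against a triangle mesh through a pinhole camera, plus
// point-to-mesh distance queries. A median-split AABB BVH keeps both
// operations tractable at depth-map resolutions.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1;  // children, or -1 for leaf
  int start = 0, count = 0;   // triangle range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> tri_order;
  const double* V;
  const int* F;
  int nv, nf;

  void tri_verts(int t, double p[3][3]) const {
    for (int v = 0; v < 3; ++v) {
      int idx = F[t + (size_t)nf * v] - 1;
      for (int d = 0; d < 3; ++d) p[v][d] = V[idx + (size_t)nv * d];
    }
  }

  int build(std::vector<int>& tris, int start, int count,
            const std::vector<double>& cent) {
    BVHNode node;
    for (int d = 0; d < 3; ++d) {
      node.bmin[d] = std::numeric_limits<double>::infinity();
      node.bmax[d] = -std::numeric_limits<double>::infinity();
    }
    for (int i = start; i < start + count; ++i) {
      double p[3][3];
      tri_verts(tris[i], p);
      for (int v = 0; v < 3; ++v)
        for (int d = 0; d < 3; ++d) {
          node.bmin[d] = std::min(node.bmin[d], p[v][d]);
          node.bmax[d] = std::max(node.bmax[d], p[v][d]);
        }
    }
    int idx = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 4) {
      nodes[idx].start = start;
      nodes[idx].count = count;
      return idx;
    }
    int axis = 0;
    double ext[3];
    for (int d = 0; d < 3; ++d) ext[d] = node.bmax[d] - node.bmin[d];
    if (ext[1] > ext[axis]) axis = 1;
    if (ext[2] > ext[axis]) axis = 2;
    int mid = start + count / 2;
    std::nth_element(tris.begin() + start, tris.begin() + mid,
                     tris.begin() + start + count,
                     [&](int a, int b) {
                       return cent[a + (size_t)nf * axis] <
                              cent[b + (size_t)nf * axis];
                     });
    int l = build(tris, start, count / 2, cent);
    int r = build(tris, mid, count - count / 2, cent);
    nodes[idx].left = l;
    nodes[idx].right = r;
    return idx;
  }

  void init(const double* Vp, const int* Fp, int nvp, int nfp) {
    V = Vp; F = Fp; nv = nvp; nf = nfp;
    tri_order.resize(nf);
    std::vector<double> cent((size_t)nf * 3);
    for (int t = 0; t < nf; ++t) {
      tri_order[t] = t;
      double p[3][3];
      tri_verts(t, p);
      for (int d = 0; d < 3; ++d)
        cent[t + (size_t)nf * d] = (p[0][d] + p[1][d] + p[2][d]) / 3.0;
    }
    nodes.reserve(2 * nf / 4 + 8);
    build(tri_order, 0, nf, cent);
  }
};

inline bool box_hit(const BVHNode& n, const double o[3], const double inv[3],
                    double tmax) {
  double t0 = 0.0, t1 = tmax;
  for (int d = 0; d < 3; ++d) {
    double ta = (n.bmin[d] - o[d]) * inv[d];
    double tb = (n.bmax[d] - o[d]) * inv[d];
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
    if (t0 > t1) return false;
  }
  return true;
}

// Moller-Trumbore; t in units of the (possibly unnormalised) direction.
inline bool tri_hit(const double p[3][3], const double o[3], const double dir[3],
                    double& t) {
  const double eps = 1e-12;
  double e1[3], e2[3];
  for (int d = 0; d < 3; ++d) {
    e1[d] = p[1][d] - p[0][d];
    e2[d] = p[2][d] - p[0][d];
  }
  double pv[3] = {dir[1] * e2[2] - dir[2] * e2[1],
                  dir[2] * e2[0] - dir[0] * e2[2],
                  dir[0] * e2[1] - dir[1] * e2[0]};
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < eps) return false;
  double inv_det = 1.0 / det;
  double tv[3] = {o[0] - p[0][0], o[1] - p[0][1], o[2] - p[0][2]};
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv_det;
  if (u < -1e-12 || u > 1 + 1e-12) return false;
  double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                  tv[2] * e1[0] - tv[0] * e1[2],
                  tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (dir[0] * qv[0] + dir[1] * qv[1] + dir[2] * qv[2]) * inv_det;
  if (v < -1e-12 || u + v > 1 + 1e-12) return false;
  t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv_det;
  return t > 1e-9;
}

void ray_query(const BVH& bvh, const double o[3], const double dir[3],
               double& best_t, int& nhits, bool count_all) {
  double inv[3];
  for (int d = 0; d < 3; ++d)
    inv[d] = (dir[d] != 0) ? 1.0 / dir[d]
                           : std::numeric_limits<double>::infinity();
  std::vector<int> stack;
  stack.reserve(64);
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVHNode& n = bvh.nodes[ni];
    double limit = count_all ? std::numeric_limits<double>::infinity() : best_t;
    if (!box_hit(n, o, inv, limit)) continue;
    if (n.left < 0) {
      for (int i = n.start; i < n.start + n.count; ++i) {
        double p[3][3], t;
        bvh.tri_verts(bvh.tri_order[i], p);
        if (tri_hit(p, o, dir, t)) {
          if (count_all) ++nhits;
          if (t < best_t) best_t = t;
        }
      }
    } else {
      stack.push_back(n.left);
      stack.push_back(n.right);
    }
  }
}

double point_tri_dist2(const double q[3], const double p[3][3]) {
  // Ericson's closest-point-on-triangle
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = p[1][d] - p[0][d];
    ac[d] = p[2][d] - p[0][d];
    ap[d] = q[d] - p[0][d];
  }
  auto dot = [](const double* a, const double* b) {
    return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
  };
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  double cp[3];
  if (d1 <= 0 && d2 <= 0) {
    for (int d = 0; d < 3; ++d) cp[d] = p[0][d];
  } else {
    double bp[3], cpv[3];
    for (int d = 0; d < 3; ++d) bp[d] = q[d] - p[1][d];
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) {
      for (int d = 0; d < 3; ++d) cp[d] = p[1][d];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int d = 0; d < 3; ++d) cp[d] = p[0][d] + v * ab[d];
      } else {
        for (int d = 0; d < 3; ++d) cpv[d] = q[d] - p[2][d];
        double d5 = dot(ab, cpv), d6 = dot(ac, cpv);
        if (d6 >= 0 && d5 <= d6) {
          for (int d = 0; d < 3; ++d) cp[d] = p[2][d];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            for (int d = 0; d < 3; ++d) cp[d] = p[0][d] + w * ac[d];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int d = 0; d < 3; ++d)
                cp[d] = p[1][d] + w * (p[2][d] - p[1][d]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int d = 0; d < 3; ++d)
                cp[d] = p[0][d] + ab[d] * v + ac[d] * w;
            }
          }
        }
      }
    }
  }
  double dx = q[0] - cp[0], dy = q[1] - cp[1], dz = q[2] - cp[2];
  return dx * dx + dy * dy + dz * dz;
}

inline double box_dist2(const BVHNode& n, const double q[3]) {
  double s = 0;
  for (int d = 0; d < 3; ++d) {
    double v = 0;
    if (q[d] < n.bmin[d]) v = n.bmin[d] - q[d];
    else if (q[d] > n.bmax[d]) v = q[d] - n.bmax[d];
    s += v * v;
  }
  return s;
}

void nearest_tri(const BVH& bvh, int ni, const double q[3], double& best2) {
  const BVHNode& n = bvh.nodes[ni];
  if (box_dist2(n, q) >= best2) return;
  if (n.left < 0) {
    for (int i = n.start; i < n.start + n.count; ++i) {
      double p[3][3];
      bvh.tri_verts(bvh.tri_order[i], p);
      best2 = std::min(best2, point_tri_dist2(q, p));
    }
  } else {
    double dl = box_dist2(bvh.nodes[n.left], q);
    double dr = box_dist2(bvh.nodes[n.right], q);
    if (dl < dr) {
      nearest_tri(bvh, n.left, q, best2);
      nearest_tri(bvh, n.right, q, best2);
    } else {
      nearest_tri(bvh, n.right, q, best2);
      nearest_tri(bvh, n.left, q, best2);
    }
  }
}

}  // namespace

// Depth map (projective z-depth) of a mesh given in the CAMERA frame
// (+z optical axis). Misses are NaN.
// [[Rcpp::export(name = ".raycast_depth")]]
NumericMatrix raycast_depth(NumericMatrix V, IntegerMatrix F, double fx,
                            double fy, double cx, double cy, int width,
                            int height) {
  BVH bvh;
  bvh.init(REAL(V), INTEGER(F), V.nrow(), F.nrow());
  NumericMatrix depth(height, width);
  std::fill(depth.begin(), depth.end(), NA_REAL);
  const double o[3] = {0, 0, 0};
  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      double dir[3] = {(u + 0.5 - cx) / fx, (v + 0.5 - cy) / fy, 1.0};
      double t = std::numeric_limits<double>::infinity();
      int nh = 0;
      ray_query(bvh, o, dir, t, nh, false);
      if (std::isfinite(t)) depth(v, u) = t;  // dir z-component is 1 => t == z
    }
  }
  return depth;
}

// Number of mesh intersections along a ray (parity test for containment).
// [[Rcpp::export(name = ".ray_hit_count")]]
int ray_hit_count(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                  NumericVector dir) {
  BVH bvh;
  bvh.init(REAL(V), INTEGER(F), V.nrow(), F.nrow());
  double o[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double t = std::numeric_limits<double>::infinity();
  int nh = 0;
  ray_query(bvh, o, d, t, nh, true);
  return nh;
}

// Unsigned distance from each query point to the mesh surface.
// [[Rcpp::export(name = ".point_mesh_distance")]]
NumericVector point_mesh_distance(NumericMatrix V, IntegerMatrix F,
                                  NumericMatrix P) {
  BVH bvh;
  bvh.init(REAL(V), INTEGER(F), V.nrow(), F.nrow());
  int n = P.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best2 = std::numeric_limits<double>::infinity();
    nearest_tri(bvh, 0, q, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}
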