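// Triangle-mesh solid kernel: measurement, containment, distance queries,
// plane sections, and field-based boolean operations with
// marching-tetrahedra polygonisation. All lengths in mm.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <queue>
#include <limits>
#include <functional>

using namespace Rcpp;

typedef std::array<double, 3> V3;

static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 sub(const V3& a, const V3& b) { return v3(a[0]-b[0], a[1]-b[1], a[2]-b[2]); }
static inline V3 add(const V3& a, const V3& b) { return v3(a[0]+b[0], a[1]+b[1], a[2]+b[2]); }
static inline V3 scl(const V3& a, double s) { return v3(a[0]*s, a[1]*s, a[2]*s); }
static inline double dot(const V3& a, const V3& b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
static inline V3 cross(const V3& a, const V3& b) {
  return v3(a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]);
}
static inline double norm2(const V3& a) { return dot(a, a); }
static inline double nrm(const V3& a) { return std::sqrt(norm2(a)); }

struct Mesh {
  std::vector<V3> v;
  std::vector<std::array<int,3> > f;
};

static Mesh as_mesh(const NumericMatrix& V, const IntegerMatrix& F) {
  Mesh m;
  m.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) m.v[i] = v3(V(i,0), V(i,1), V(i,2));
  m.f.resize(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    m.f[i][0] = F(i,0) - 1; m.f[i][1] = F(i,1) - 1; m.f[i][2] = F(i,2) - 1;
  }
  return m;
}

// ---------------------------------------------------------------- mesh stats

struct EdgeKey {
  int64_t k;
  EdgeKey(int a, int b) {
    int lo = std::min(a, b), hi = std::max(a, b);
    k = (int64_t)lo * 0x40000000LL + hi;
  }
};

// [[Rcpp::export]]
List cpp_mesh_stats(NumericMatrix V, IntegerMatrix F) {
  Mesh m = as_mesh(V, F);
  const int nf = (int)m.f.size();
  double vol = 0.0, area = 0.0;
  V3 lo = v3(R_PosInf, R_PosInf, R_PosInf), hi = v3(R_NegInf, R_NegInf, R_NegInf);
  for (size_t i = 0; i < m.v.size(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], m.v[i][k]);
      hi[k] = std::max(hi[k], m.v[i][k]);
    }
  for (int i = 0; i < nf; ++i) {
    const V3 &a = m.v[m.f[i][0]], &b = m.v[m.f[i][1]], &c = m.v[m.f[i][2]];
    vol += dot(a, cross(b, c)) / 6.0;
    area += 0.5 * nrm(cross(sub(b, a), sub(c, a)));
  }
  // edge use counts: watertight manifold = each undirected edge used exactly
  // twice, once per direction
  std::unordered_map<int64_t, std::pair<int,int> > edges; // (fwd, bwd) counts
  edges.reserve(nf * 3);
  bool ok_manifold = true;
  for (int i = 0; i < nf; ++i) {
    for (int e = 0; e < 3; ++e) {
      int a = m.f[i][e], b = m.f[i][(e+1)%3];
      if (a == b) { ok_manifold = false; continue; }
      int lo_i = std::min(a,b), hi_i = std::max(a,b);
      int64_t key = (int64_t)lo_i * 0x40000000LL + hi_i;
      std::pair<int,int>& cnt = edges[key];
      if (a < b) cnt.first++; else cnt.second++;
    }
  }
  bool watertight = ok_manifold;
  for (std::unordered_map<int64_t, std::pair<int,int> >::iterator it = edges.begin();
       it != edges.end(); ++it) {
    if (it->second.first != 1 || it->second.second != 1) { watertight = false; break; }
  }
  // connected components over faces sharing an edge
  std::vector<int> parent(nf);
  for (int i = 0; i < nf; ++i) parent[i] = i;
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int operator()(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } find(parent);
  std::unordered_map<int64_t, int> first_face;
  first_face.reserve(nf * 3);
  for (int i = 0; i < nf; ++i) {
    for (int e = 0; e < 3; ++e) {
      int a = m.f[i][e], b = m.f[i][(e+1)%3];
      int lo_i = std::min(a,b), hi_i = std::max(a,b);
      int64_t key = (int64_t)lo_i * 0x40000000LL + hi_i;
      std::unordered_map<int64_t,int>::iterator it = first_face.find(key);
      if (it == first_face.end()) first_face[key] = i;
      else {
        int ra = find(i), rb = find(it->second);
        if (ra != rb) parent[ra] = rb;
      }
    }
  }
  int ncomp = 0;
  for (int i = 0; i < nf; ++i) if (find(i) == i) ncomp++;
  return List::create(
    _["volume"] = vol, _["area"] = area,
    _["bbox_min"] = NumericVector::create(lo[0], lo[1], lo[2]),
    _["bbox_max"] = NumericVector::create(hi[0], hi[1], hi[2]),
    _["watertight"] = watertight, _["components"] = ncomp,
    _["n_vertices"] = (int)m.v.size(), _["n_faces"] = nf);
}

// component id (1-based) per face, over shared-edge connectivity
// [[Rcpp::export]]
IntegerVector cpp_face_components(NumericMatrix V, IntegerMatrix F) {
  Mesh m = as_mesh(V, F);
  int nf = (int)m.f.size();
  std::vector<int> parent(nf);
  for (int i = 0; i < nf; ++i) parent[i] = i;
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int operator()(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } find(parent);
  std::unordered_map<int64_t, int> first_face;
  first_face.reserve(nf * 3);
  for (int i = 0; i < nf; ++i) {
    for (int e = 0; e < 3; ++e) {
      int a = m.f[i][e], b = m.f[i][(e+1)%3];
      int lo = std::min(a,b), hi = std::max(a,b);
      int64_t key = (int64_t)lo * 0x40000000LL + hi;
      std::unordered_map<int64_t,int>::iterator it = first_face.find(key);
      if (it == first_face.end()) first_face[key] = i;
      else {
        int ra = find(i), rb = find(it->second);
        if (ra != rb) parent[ra] = rb;
      }
    }
  }
  std::unordered_map<int,int> remap;
  IntegerVector out(nf);
  int next_id = 0;
  for (int i = 0; i < nf; ++i) {
    int r = find(i);
    std::unordered_map<int,int>::iterator it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next_id; out[i] = next_id; }
    else out[i] = it->second;
  }
  return out;
}

// ------------------------------------------------------------ point in mesh

static inline bool ray_hit_t(const V3& o, const V3& d, const V3& a, const V3& b,
                             const V3& c, double& t) {
  // Moller-Trumbore, front/back both count
  V3 e1 = sub(b, a), e2 = sub(c, a);
  V3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  V3 tv = sub(o, a);
  double u = dot(tv, p) * inv;
  if (u < 0.0 || u > 1.0) return false;
  V3 q = cross(tv, e1);
  double v = dot(d, q) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  t = dot(e2, q) * inv;
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P, NumericVector dir) {
  Mesh m = as_mesh(V, F);
  V3 d = v3(dir[0], dir[1], dir[2]);
  double dn = nrm(d);
  d = scl(d, 1.0 / dn);
  int np = P.nrow();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    V3 o = v3(P(i,0), P(i,1), P(i,2));
    int hits = 0;
    double t;
    for (size_t j = 0; j < m.f.size(); ++j) {
      if (ray_hit_t(o, d, m.v[m.f[j][0]], m.v[m.f[j][1]], m.v[m.f[j][2]], t) && t > 0)
        hits++;
    }
    out[i] = (hits % 2) == 1;
  }
  return out;
}

// --------------------------------------------------- distance primitives

static double point_tri_d2(const V3& p, const V3& a, const V3& b, const V3& c) {
  // Ericson, Real-Time Collision Detection
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return norm2(ap);
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return norm2(bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    return norm2(sub(ap, scl(ab, t)));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return norm2(cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    return norm2(sub(ap, scl(ac, t)));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return norm2(sub(bp, scl(sub(c, b), t)));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = add(a, add(scl(ab, v), scl(ac, w)));
  return norm2(sub(p, q));
}

static double seg_seg_d2(const V3& p1, const V3& q1, const V3& p2, const V3& q2) {
  V3 d1 = sub(q1, p1), d2 = sub(q2, p2), r = sub(p1, p2);
  double a = norm2(d1), e = norm2(d2), f = dot(d2, r);
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) return norm2(r);
  if (a <= EPS) { s = 0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot(d1, r);
    if (e <= EPS) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot(d1, d2), denom = a * e - b * b;
      if (denom > EPS) s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      else s = 0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  V3 c1 = add(p1, scl(d1, s)), c2 = add(p2, scl(d2, t));
  return norm2(sub(c1, c2));
}

static double seg_tri_d2(const V3& p, const V3& q, const V3& a, const V3& b, const V3& c) {
  // zero if the segment pierces the triangle
  V3 n = cross(sub(b, a), sub(c, a));
  double dp = dot(n, sub(p, a)), dq = dot(n, sub(q, a));
  if (dp * dq < 0) {
    double t = dp / (dp - dq);
    V3 x = add(p, scl(sub(q, p), t));
    // inside test via barycentric signs
    V3 n1 = cross(sub(b, a), sub(x, a));
    V3 n2 = cross(sub(c, b), sub(x, b));
    V3 n3 = cross(sub(a, c), sub(x, c));
    if (dot(n1, n) >= 0 && dot(n2, n) >= 0 && dot(n3, n) >= 0) return 0.0;
  }
  double d2 = std::min(point_tri_d2(p, a, b, c), point_tri_d2(q, a, b, c));
  d2 = std::min(d2, seg_seg_d2(p, q, a, b));
  d2 = std::min(d2, seg_seg_d2(p, q, b, c));
  d2 = std::min(d2, seg_seg_d2(p, q, c, a));
  return d2;
}

static double tri_tri_d2(const V3& a0, const V3& a1, const V3& a2,
                         const V3& b0, const V3& b1, const V3& b2) {
  double d2 = seg_tri_d2(a0, a1, b0, b1, b2);
  if (d2 == 0) return 0;
  d2 = std::min(d2, seg_tri_d2(a1, a2, b0, b1, b2));
  d2 = std::min(d2, seg_tri_d2(a2, a0, b0, b1, b2));
  d2 = std::min(d2, seg_tri_d2(b0, b1, a0, a1, a2));
  d2 = std::min(d2, seg_tri_d2(b1, b2, a0, a1, a2));
  d2 = std::min(d2, seg_tri_d2(b2, b0, a0, a1, a2));
  return d2;
}

// --------------------------------------------------------------------- BVH

struct BVHNode {
  V3 lo, hi;
  int left, right;   // children, or -1
  int begin, end;    // leaf triangle range in order[]
};

struct BVH {
  const Mesh* m;
  std::vector<BVHNode> nodes;
  std::vector<int> order;
};

static void bvh_build_rec(BVH& t, int node, int begin, int end,
                          const std::vector<V3>& cent) {
  BVHNode& nd = t.nodes[node];
  nd.lo = v3(R_PosInf, R_PosInf, R_PosInf);
  nd.hi = v3(R_NegInf, R_NegInf, R_NegInf);
  for (int i = begin; i < end; ++i) {
    const std::array<int,3>& f = t.m->f[t.order[i]];
    for (int k = 0; k < 3; ++k) {
      const V3& p = t.m->v[f[k]];
      for (int d = 0; d < 3; ++d) {
        nd.lo[d] = std::min(nd.lo[d], p[d]);
        nd.hi[d] = std::max(nd.hi[d], p[d]);
      }
    }
  }
  nd.begin = begin; nd.end = end; nd.left = nd.right = -1;
  if (end - begin <= 4) return;
  int axis = 0;
  V3 ext = sub(nd.hi, nd.lo);
  if (ext[1] > ext[axis]) axis = 1;
  if (ext[2] > ext[axis]) axis = 2;
  int mid = (begin + end) / 2;
  std::nth_element(t.order.begin() + begin, t.order.begin() + mid,
                   t.order.begin() + end,
                   [&](int a, int b) { return cent[a][axis] < cent[b][axis]; });
  int li = (int)t.nodes.size(); t.nodes.push_back(BVHNode());
  int ri = (int)t.nodes.size(); t.nodes.push_back(BVHNode());
  t.nodes[node].left = li; t.nodes[node].right = ri;
  bvh_build_rec(t, li, begin, mid, cent);
  bvh_build_rec(t, ri, mid, end, cent);
}

static void bvh_build(BVH& t, const Mesh& m) {
  t.m = &m;
  int nf = (int)m.f.size();
  t.order.resize(nf);
  std::vector<V3> cent(nf);
  for (int i = 0; i < nf; ++i) {
    t.order[i] = i;
    const std::array<int,3>& f = m.f[i];
    cent[i] = scl(add(add(m.v[f[0]], m.v[f[1]]), m.v[f[2]]), 1.0/3.0);
  }
  t.nodes.clear();
  t.nodes.push_back(BVHNode());
  bvh_build_rec(t, 0, 0, nf, cent);
}

static double box_box_d2(const BVHNode& a, const BVHNode& b) {
  double d2 = 0;
  for (int k = 0; k < 3; ++k) {
    double d = std::max(0.0, std::max(a.lo[k] - b.hi[k], b.lo[k] - a.hi[k]));
    d2 += d * d;
  }
  return d2;
}

static void bvh_min_rec(const BVH& A, const BVH& B, int na, int nb, double& best) {
  const BVHNode& a = A.nodes[na];
  const BVHNode& b = B.nodes[nb];
  if (box_box_d2(a, b) >= best) return;
  bool leafA = a.left < 0, leafB = b.left < 0;
  if (leafA && leafB) {
    for (int i = a.begin; i < a.end; ++i) {
      const std::array<int,3>& fa = A.m->f[A.order[i]];
      for (int j = b.begin; j < b.end; ++j) {
        const std::array<int,3>& fb = B.m->f[B.order[j]];
        double d2 = tri_tri_d2(A.m->v[fa[0]], A.m->v[fa[1]], A.m->v[fa[2]],
                               B.m->v[fb[0]], B.m->v[fb[1]], B.m->v[fb[2]]);
        if (d2 < best) best = d2;
        if (best == 0) return;
      }
    }
    return;
  }
  if (leafB || (!leafA && (a.hi[0]-a.lo[0]+a.hi[1]-a.lo[1]+a.hi[2]-a.lo[2]) >
                         (b.hi[0]-b.lo[0]+b.hi[1]-b.lo[1]+b.hi[2]-b.lo[2]))) {
    // descend A, nearer child first
    double dl = box_box_d2(A.nodes[a.left], b), dr = box_box_d2(A.nodes[a.right], b);
    if (dl < dr) { bvh_min_rec(A, B, a.left, nb, best); bvh_min_rec(A, B, a.right, nb, best); }
    else { bvh_min_rec(A, B, a.right, nb, best); bvh_min_rec(A, B, a.left, nb, best); }
  } else {
    double dl = box_box_d2(a, B.nodes[b.left]), dr = box_box_d2(a, B.nodes[b.right]);
    if (dl < dr) { bvh_min_rec(A, B, na, b.left, best); bvh_min_rec(A, B, na, b.right, best); }
    else { bvh_min_rec(A, B, na, b.right, best); bvh_min_rec(A, B, na, b.left, best); }
  }
}

// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix VA, IntegerMatrix FA,
                        NumericMatrix VB, IntegerMatrix FB) {
  Mesh ma = as_mesh(VA, FA), mb = as_mesh(VB, FB);
  BVH A, B;
  bvh_build(A, ma);
  bvh_build(B, mb);
  double best = R_PosInf;
  bvh_min_rec(A, B, 0, 0, best);
  return std::sqrt(best);
}

// ------------------------------------------------------------- plane slice

// [[Rcpp::export]]
NumericMatrix cpp_slice(NumericMatrix V, IntegerMatrix F,
                        NumericVector p0v, NumericVector nv) {
  Mesh m = as_mesh(V, F);
  V3 p0 = v3(p0v[0], p0v[1], p0v[2]);
  V3 n = v3(nv[0], nv[1], nv[2]);
  n = scl(n, 1.0 / nrm(n));
  std::vector<double> out; // x1 y1 z1 x2 y2 z2 per row, oriented CCW wrt n
  for (size_t i = 0; i < m.f.size(); ++i) {
    const V3 &a = m.v[m.f[i][0]], &b = m.v[m.f[i][1]], &c = m.v[m.f[i][2]];
    double da = dot(n, sub(a, p0)), db = dot(n, sub(b, p0)), dc = dot(n, sub(c, p0));
    const V3* P[3] = { &a, &b, &c };
    double D[3] = { da, db, dc };
    std::vector<V3> pts;
    for (int e = 0; e < 3; ++e) {
      double d1 = D[e], d2 = D[(e+1)%3];
      if ((d1 < 0 && d2 >= 0) || (d1 >= 0 && d2 < 0)) {
        double t = d1 / (d1 - d2);
        pts.push_back(add(*P[e], scl(sub(*P[(e+1)%3], *P[e]), t)));
      }
    }
    if (pts.size() != 2) continue;
    V3 tn = cross(sub(b, a), sub(c, a));
    V3 dref = cross(n, tn); // points along the CCW boundary of (solid ∩ plane)
    V3 seg = sub(pts[1], pts[0]);
    if (dot(seg, dref) < 0) std::swap(pts[0], pts[1]);
    for (int k = 0; k < 3; ++k) out.push_back(pts[0][k]);
    for (int k = 0; k < 3; ++k) out.push_back(pts[1][k]);
  }
  NumericMatrix res((int)(out.size() / 6), 6);
  for (int i = 0; i < res.nrow(); ++i)
    for (int j = 0; j < 6; ++j) res(i, j) = out[i * 6 + j];
  return res;
}

// ----------------------------------------------------------- dihedral stats

// [[Rcpp::export]]
List cpp_dihedral_stats(NumericMatrix V, IntegerMatrix F, double min_area) {
  Mesh m = as_mesh(V, F);
  int nf = (int)m.f.size();
  std::vector<V3> nrms(nf);
  std::vector<V3> cent(nf);
  std::vector<double> areas(nf);
  for (int i = 0; i < nf; ++i) {
    const V3 &a = m.v[m.f[i][0]], &b = m.v[m.f[i][1]], &c = m.v[m.f[i][2]];
    V3 cr = cross(sub(b, a), sub(c, a));
    double ar = 0.5 * nrm(cr);
    areas[i] = ar;
    nrms[i] = ar > 0 ? scl(cr, 0.5 / ar) : v3(0,0,1);
    cent[i] = scl(add(add(a, b), c), 1.0/3.0);
  }
  std::unordered_map<int64_t, int> half;
  half.reserve(nf * 3);
  double max_convex = 0.0;
  for (int i = 0; i < nf; ++i) {
    if (areas[i] < min_area) continue;
    for (int e = 0; e < 3; ++e) {
      int a = m.f[i][e], b = m.f[i][(e+1)%3];
      int lo = std::min(a,b), hi = std::max(a,b);
      int64_t key = (int64_t)lo * 0x40000000LL + hi;
      std::unordered_map<int64_t,int>::iterator it = half.find(key);
      if (it == half.end()) { half[key] = i; continue; }
      int j = it->second;
      if (areas[j] < min_area) continue;
      double cosang = std::max(-1.0, std::min(1.0, dot(nrms[i], nrms[j])));
      double ang = std::acos(cosang); // 0 = coplanar
      // convex if the other centroid lies below this face plane
      bool convex = dot(nrms[i], sub(cent[j], cent[i])) < 0;
      if (convex && ang > max_convex) max_convex = ang;
    }
  }
  return List::create(_["max_convex_angle_deg"] = max_convex * 180.0 / M_PI);
}

// =================================================================== fields

struct Grid {
  V3 o;          // node (0,0,0) position
  double h;
  int nx, ny, nz; // node counts
  inline size_t idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
  }
  inline size_t n() const { return (size_t)nx * ny * nz; }
};

static const float FBIG = 1e6f;

// parity sign along one axis; votes[n] incremented where inside
static void parity_axis(const Mesh& m, const Grid& g, int axis,
                        std::vector<uint8_t>& votes) {
  // axis: ray direction; columns over the two other axes
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  int n1 = (a1 == 0 ? g.nx : (a1 == 1 ? g.ny : g.nz));
  int n2 = (a2 == 0 ? g.nx : (a2 == 1 ? g.ny : g.nz));
  int n0 = (axis == 0 ? g.nx : (axis == 1 ? g.ny : g.nz));
  // bin triangles by covered columns
  std::vector<std::vector<int> > bins((size_t)n1 * n2);
  for (size_t t = 0; t < m.f.size(); ++t) {
    const V3 &A = m.v[m.f[t][0]], &B = m.v[m.f[t][1]], &C = m.v[m.f[t][2]];
    double lo1 = std::min(A[a1], std::min(B[a1], C[a1]));
    double hi1 = std::max(A[a1], std::max(B[a1], C[a1]));
    double lo2 = std::min(A[a2], std::min(B[a2], C[a2]));
    double hi2 = std::max(A[a2], std::max(B[a2], C[a2]));
    int i1a = std::max(0, (int)std::ceil((lo1 - g.o[a1]) / g.h));
    int i1b = std::min(n1 - 1, (int)std::floor((hi1 - g.o[a1]) / g.h));
    int i2a = std::max(0, (int)std::ceil((lo2 - g.o[a2]) / g.h));
    int i2b = std::min(n2 - 1, (int)std::floor((hi2 - g.o[a2]) / g.h));
    for (int j = i2a; j <= i2b; ++j)
      for (int i = i1a; i <= i1b; ++i)
        bins[(size_t)i + (size_t)n1 * j].push_back((int)t);
  }
  std::vector<double> xs;
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      const std::vector<int>& tri = bins[(size_t)i + (size_t)n1 * j];
      if (tri.empty()) continue;
      double c1 = g.o[a1] + g.h * i, c2 = g.o[a2] + g.h * j;
      xs.clear();
      for (size_t q = 0; q < tri.size(); ++q) {
        const std::array<int,3>& f = m.f[tri[q]];
        const V3 &A = m.v[f[0]], &B = m.v[f[1]], &C = m.v[f[2]];
        // intersect line {a1=c1, a2=c2} with triangle: 2D barycentric in (a1,a2)
        double x1 = A[a1], y1 = A[a2], x2 = B[a1], y2 = B[a2], x3 = C[a1], y3 = C[a2];
        double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
        if (std::fabs(det) < 1e-18) continue;
        double l1 = ((y2 - y3) * (c1 - x3) + (x3 - x2) * (c2 - y3)) / det;
        double l2 = ((y3 - y1) * (c1 - x3) + (x1 - x3) * (c2 - y3)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        xs.push_back(l1 * A[axis] + l2 * B[axis] + l3 * C[axis]);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // walk nodes of the column
      size_t ci = 0;
      int parity = 0;
      for (int k0 = 0; k0 < n0; ++k0) {
        double x = g.o[axis] + g.h * k0;
        while (ci < xs.size() && xs[ci] < x) { parity ^= 1; ++ci; }
        if (parity) {
          int ii[3];
          ii[axis] = k0; ii[a1] = i; ii[a2] = j;
          votes[g.idx(ii[0], ii[1], ii[2])]++;
        }
      }
    }
  }
}

// capped point-to-mesh distance via best-first BVH descent; returns dmax if
// nothing is closer
static double point_box_d2(const V3& p, const BVHNode& b) {
  double d2 = 0;
  for (int k = 0; k < 3; ++k) {
    double d = std::max(0.0, std::max(b.lo[k] - p[k], p[k] - b.hi[k]));
    d2 += d * d;
  }
  return d2;
}

static void bvh_point_rec(const BVH& T, int ni, const V3& p, double& best2) {
  const BVHNode& nd = T.nodes[ni];
  if (point_box_d2(p, nd) >= best2) return;
  if (nd.left < 0) {
    for (int i = nd.begin; i < nd.end; ++i) {
      const std::array<int,3>& f = T.m->f[T.order[i]];
      double d2 = point_tri_d2(p, T.m->v[f[0]], T.m->v[f[1]], T.m->v[f[2]]);
      if (d2 < best2) best2 = d2;
    }
    return;
  }
  double dl = point_box_d2(p, T.nodes[nd.left]);
  double dr = point_box_d2(p, T.nodes[nd.right]);
  if (dl < dr) { bvh_point_rec(T, nd.left, p, best2); bvh_point_rec(T, nd.right, p, best2); }
  else { bvh_point_rec(T, nd.right, p, best2); bvh_point_rec(T, nd.left, p, best2); }
}

static void mesh_bbox(const Mesh& m, V3& lo, V3& hi);

// signed field of one mesh on grid; distances resolved exactly within `band`
// of the surface, saturated to +/-FBIG beyond. Only nodes within the mesh's
// bounding box (plus band) are evaluated; `out` must be pre-filled with
// +FBIG over the full grid.
static void mesh_field(const Mesh& m, const Grid& g, double band,
                       std::vector<float>& out) {
  out.assign(g.n(), FBIG);
  V3 lo, hi;
  mesh_bbox(m, lo, hi);
  double pad = band + 3.0 * g.h;
  int i0[3], i1[3];
  for (int k = 0; k < 3; ++k) {
    int nk = (k == 0 ? g.nx : (k == 1 ? g.ny : g.nz));
    i0[k] = std::max(0, (int)std::floor((lo[k] - pad - g.o[k]) / g.h));
    i1[k] = std::min(nk - 1, (int)std::ceil((hi[k] + pad - g.o[k]) / g.h));
  }
  std::vector<uint8_t> votes(g.n(), 0);
  for (int ax = 0; ax < 3; ++ax) parity_axis(m, g, ax, votes);
  BVH T;
  bvh_build(T, m);
  double dmax = band + 2.0 * g.h;
  double dmax2 = dmax * dmax;
  for (int k = i0[2]; k <= i1[2]; ++k)
    for (int j = i0[1]; j <= i1[1]; ++j)
      for (int i = i0[0]; i <= i1[0]; ++i) {
        size_t id = g.idx(i, j, k);
        bool inside = votes[id] >= 2;
        V3 p = v3(g.o[0] + g.h * i, g.o[1] + g.h * j, g.o[2] + g.h * k);
        double best2 = dmax2;
        bvh_point_rec(T, 0, p, best2);
        float d = (best2 >= dmax2 * 0.999999) ? FBIG : (float)std::sqrt(best2);
        out[id] = inside ? -d : d;
      }
}

// marching tetrahedra over field (iso already subtracted by caller)
static void march_tets(const std::vector<float>& f, const Grid& g,
                       Mesh& out) {
  // Kuhn decomposition: 6 tets per cell, consistent across cells
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
  };
  std::unordered_map<int64_t, int> vmap;
  vmap.reserve(1 << 16);
  out.v.clear(); out.f.clear();
  std::vector<size_t> corner_id(4);
  std::vector<float> cv(4);
  // edge vertex lookup
  const double tclamp = 0.01;
  for (int k = 0; k + 1 < g.nz; ++k) {
    for (int j = 0; j + 1 < g.ny; ++j) {
      for (int i = 0; i + 1 < g.nx; ++i) {
        // quick cull
        float mn = FBIG, mx = -FBIG;
        for (int c = 0; c < 8; ++c) {
          float val = f[g.idx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1))];
          mn = std::min(mn, val); mx = std::max(mx, val);
        }
        if (mn > 0 || mx <= 0) continue;
        for (int p = 0; p < 6; ++p) {
          int ii[4][3];
          ii[0][0] = i; ii[0][1] = j; ii[0][2] = k;
          for (int s = 1; s <= 3; ++s) {
            ii[s][0] = ii[s-1][0]; ii[s][1] = ii[s-1][1]; ii[s][2] = ii[s-1][2];
            ii[s][perms[p][s-1]] += 1;
          }
          size_t id[4];
          float val[4];
          int neg[4], pos[4], nneg = 0, npos = 0;
          for (int s = 0; s < 4; ++s) {
            id[s] = g.idx(ii[s][0], ii[s][1], ii[s][2]);
            val[s] = f[id[s]];
            if (val[s] <= 0) neg[nneg++] = s; else pos[npos++] = s;
          }
          if (nneg == 0 || nneg == 4) continue;
          // emit vertex on edge (a neg, b pos)
          auto edge_vertex = [&](int a, int b) -> int {
            int64_t ka = (int64_t)id[a], kb = (int64_t)id[b];
            int64_t key = ka < kb ? ka * 0x100000000LL + kb : kb * 0x100000000LL + ka;
            std::unordered_map<int64_t,int>::iterator it = vmap.find(key);
            if (it != vmap.end()) return it->second;
            double fa = val[a], fb = val[b];
            double t = fa / (fa - fb);
            if (t < tclamp) t = tclamp;
            if (t > 1 - tclamp) t = 1 - tclamp;
            V3 pa = v3(g.o[0] + g.h * ii[a][0], g.o[1] + g.h * ii[a][1], g.o[2] + g.h * ii[a][2]);
            V3 pb = v3(g.o[0] + g.h * ii[b][0], g.o[1] + g.h * ii[b][1], g.o[2] + g.h * ii[b][2]);
            V3 pq = add(pa, scl(sub(pb, pa), t));
            int vi = (int)out.v.size();
            out.v.push_back(pq);
            vmap[key] = vi;
            return vi;
          };
          // orientation helper: outward = from neg side to pos side
          V3 cneg = v3(0,0,0), cpos = v3(0,0,0);
          for (int s = 0; s < nneg; ++s)
            cneg = add(cneg, v3(g.o[0]+g.h*ii[neg[s]][0], g.o[1]+g.h*ii[neg[s]][1], g.o[2]+g.h*ii[neg[s]][2]));
          for (int s = 0; s < npos; ++s)
            cpos = add(cpos, v3(g.o[0]+g.h*ii[pos[s]][0], g.o[1]+g.h*ii[pos[s]][1], g.o[2]+g.h*ii[pos[s]][2]));
          cneg = scl(cneg, 1.0 / nneg);
          cpos = scl(cpos, 1.0 / npos);
          V3 outdir = sub(cpos, cneg);
          auto emit = [&](int v0, int v1, int v2) {
            if (v0 == v1 || v1 == v2 || v0 == v2) return;
            V3 nn = cross(sub(out.v[v1], out.v[v0]), sub(out.v[v2], out.v[v0]));
            std::array<int,3> tri;
            if (dot(nn, outdir) >= 0) { tri[0]=v0; tri[1]=v1; tri[2]=v2; }
            else { tri[0]=v0; tri[1]=v2; tri[2]=v1; }
            out.f.push_back(tri);
          };
          if (nneg == 1) {
            int a = neg[0];
            emit(edge_vertex(a, pos[0]), edge_vertex(a, pos[1]), edge_vertex(a, pos[2]));
          } else if (nneg == 3) {
            int b = pos[0];
            emit(edge_vertex(neg[0], b), edge_vertex(neg[1], b), edge_vertex(neg[2], b));
          } else {
            // 2 in, 2 out: quad
            int a0 = neg[0], a1 = neg[1], b0 = pos[0], b1 = pos[1];
            int q00 = edge_vertex(a0, b0), q01 = edge_vertex(a0, b1);
            int q10 = edge_vertex(a1, b0), q11 = edge_vertex(a1, b1);
            emit(q00, q01, q11);
            emit(q00, q11, q10);
          }
        }
      }
    }
  }
}

static Grid make_grid(const V3& lo, const V3& hi, double voxel, double pad,
                      double jit_seed) {
  Grid g;
  g.h = voxel;
  // deterministic irrational-ish jitter keeps nodes (and scanline rays) off
  // constructed planes; the input-dependent seed decorrelates successive
  // boolean passes, whose vertices would otherwise lie exactly on grid edges
  double j0 = 0.01234567891 + jit_seed * 0.7312385962;
  double j1 = 0.02345678912 + jit_seed * 0.5172097323;
  double j2 = 0.03456789123 + jit_seed * 0.2931834126;
  V3 jit = v3(j0 - 0.23 * std::floor(j0 / 0.23),
              j1 - 0.23 * std::floor(j1 / 0.23),
              j2 - 0.23 * std::floor(j2 / 0.23));
  for (int k = 0; k < 3; ++k) g.o[k] = lo[k] - pad - voxel * (1.0 + jit[k]);
  g.nx = (int)std::ceil((hi[0] + pad - g.o[0]) / voxel) + 2;
  g.ny = (int)std::ceil((hi[1] + pad - g.o[1]) / voxel) + 2;
  g.nz = (int)std::ceil((hi[2] + pad - g.o[2]) / voxel) + 2;
  if (g.n() > 80000000ULL) stop("CSG grid too large (%d x %d x %d nodes); increase voxel size", g.nx, g.ny, g.nz);
  return g;
}

static void mesh_bbox(const Mesh& m, V3& lo, V3& hi) {
  lo = v3(R_PosInf, R_PosInf, R_PosInf);
  hi = v3(R_NegInf, R_NegInf, R_NegInf);
  for (size_t i = 0; i < m.v.size(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], m.v[i][k]);
      hi[k] = std::max(hi[k], m.v[i][k]);
    }
}

static List mesh_to_R(const Mesh& m) {
  NumericMatrix V((int)m.v.size(), 3);
  for (int i = 0; i < (int)m.v.size(); ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = m.v[i][k];
  IntegerMatrix F((int)m.f.size(), 3);
  for (int i = 0; i < (int)m.f.size(); ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = m.f[i][k] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// n-ary CSG: union of `add` meshes minus union of `sub` meshes
// [[Rcpp::export]]
List cpp_csg(List add, List sub, double voxel, double band) {
  std::vector<Mesh> adds, subs;
  for (int i = 0; i < add.size(); ++i) {
    List mi = add[i];
    adds.push_back(as_mesh(as<NumericMatrix>(mi["vertices"]), as<IntegerMatrix>(mi["faces"])));
  }
  for (int i = 0; i < sub.size(); ++i) {
    List mi = sub[i];
    subs.push_back(as_mesh(as<NumericMatrix>(mi["vertices"]), as<IntegerMatrix>(mi["faces"])));
  }
  if (adds.empty()) stop("CSG needs at least one positive solid");
  V3 lo, hi, l2, h2;
  mesh_bbox(adds[0], lo, hi);
  size_t tot = 0;
  for (size_t i = 0; i < adds.size(); ++i) tot += adds[i].v.size();
  for (size_t i = 0; i < subs.size(); ++i) tot += subs[i].v.size();
  for (size_t i = 1; i < adds.size(); ++i) {
    mesh_bbox(adds[i], l2, h2);
    for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], l2[k]); hi[k] = std::max(hi[k], h2[k]); }
  }
  double sraw = (double)tot * 0.6180339887;
  double seed = sraw - std::floor(sraw);
  Grid g = make_grid(lo, hi, voxel, 2 * voxel, seed);
  std::vector<float> comb, fi;
  for (size_t i = 0; i < adds.size(); ++i) {
    mesh_field(adds[i], g, band, fi);
    if (i == 0) comb = fi;
    else for (size_t q = 0; q < comb.size(); ++q) comb[q] = std::min(comb[q], fi[q]);
  }
  for (size_t i = 0; i < subs.size(); ++i) {
    mesh_field(subs[i], g, band, fi);
    for (size_t q = 0; q < comb.size(); ++q) comb[q] = std::max(comb[q], -fi[q]);
  }
  Mesh out;
  march_tets(comb, g, out);
  return mesh_to_R(out);
}

// offset (positive = dilate, negative = erode) via iso-surface extraction
// [[Rcpp::export]]
List cpp_offset(NumericMatrix V, IntegerMatrix F, double offset, double voxel) {
  Mesh m = as_mesh(V, F);
  V3 lo, hi;
  mesh_bbox(m, lo, hi);
  double pad = std::max(0.0, offset) + 3 * voxel;
  double sraw = (double)m.v.size() * 0.6180339887;
  double seed = sraw - std::floor(sraw);
  Grid g = make_grid(lo, hi, voxel, pad, seed);
  double band = std::fabs(offset) + 3 * voxel;
  std::vector<float> f;
  mesh_field(m, g, band, f);
  for (size_t q = 0; q < f.size(); ++q) f[q] = (float)(f[q] - offset);
  Mesh out;
  march_tets(f, g, out);
  return mesh_to_R(out);
}

// remesh (field resample at iso 0) — used to regularise primitive output
// [[Rcpp::export]]
List cpp_remesh(NumericMatrix V, IntegerMatrix F, double voxel) {
  return cpp_offset(V, F, 0.0, voxel);
}
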