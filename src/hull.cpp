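// Incremental quickhull-style 3D convex hull plus an exact convex-polytope
// intersection volume (candidate-vertex construction). Written for the small
// point sets this package deals in (tens of loci / monomers), favouring
// robustness and zero external dependencies over asymptotic cleverness.

#include "hull.h"
#include <cmath>
#include <algorithm>
#include <utility>
#include <map>

namespace nucleome {

static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double vnorm(const Vec3& a) { return std::sqrt(vdot(a, a)); }

// Unit outward plane through face (a,b,c); outward = away from `interior`.
static bool face_plane(const Vec3& a, const Vec3& b, const Vec3& c,
                       const Vec3& interior, std::array<double, 4>& plane,
                       double eps) {
  Vec3 n = vcross(vsub(b, a), vsub(c, a));
  double len = vnorm(n);
  if (len < eps) return false;
  n.x /= len; n.y /= len; n.z /= len;
  double d = vdot(n, a);
  if (vdot(n, interior) > d) { n.x = -n.x; n.y = -n.y; n.z = -n.z; d = -d; }
  plane = {n.x, n.y, n.z, d};
  return true;
}

bool build_hull(const std::vector<Vec3>& pts, Hull& hull) {
  const int n = static_cast<int>(pts.size());
  hull.faces.clear();
  hull.planes.clear();
  hull.is_vertex.assign(n, 0);
  hull.volume = 0.0;
  hull.ok = false;
  if (n < 4) return false;

  double lo[3] = {pts[0].x, pts[0].y, pts[0].z};
  double hi[3] = {pts[0].x, pts[0].y, pts[0].z};
  for (const Vec3& p : pts) {
    lo[0] = std::min(lo[0], p.x); hi[0] = std::max(hi[0], p.x);
    lo[1] = std::min(lo[1], p.y); hi[1] = std::max(hi[1], p.y);
    lo[2] = std::min(lo[2], p.z); hi[2] = std::max(hi[2], p.z);
  }
  double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1.0});
  const double eps = 1e-9 * span;
  hull.eps = eps;

  // Initial simplex: two extremes, the point farthest from their line, the
  // point farthest from their plane.
  int i0 = 0, i1 = 0;
  if (n <= 200) {
    double best2 = -1.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d2 = vdot(vsub(pts[i], pts[j]), vsub(pts[i], pts[j]));
        if (d2 > best2) { best2 = d2; i0 = i; i1 = j; }
      }
    if (best2 < eps * eps) return false;
  } else {
    // axis-extreme seeding is enough for big inputs
    for (int i = 1; i < n; ++i) {
      if (pts[i].x < pts[i0].x) i0 = i;
      if (pts[i].x > pts[i1].x) i1 = i;
    }
    if (i0 == i1) return false;
  }
  double best;

  Vec3 dir = vsub(pts[i1], pts[i0]);
  double dlen = vnorm(dir);
  if (dlen < eps) return false;
  int i2 = -1;
  best = eps;
  for (int i = 0; i < n; ++i) {
    Vec3 w = vcross(dir, vsub(pts[i], pts[i0]));
    double h = vnorm(w) / dlen;
    if (h > best) { best = h; i2 = i; }
  }
  if (i2 < 0) return false;

  Vec3 nrm = vcross(dir, vsub(pts[i2], pts[i0]));
  double nlen = vnorm(nrm);
  int i3 = -1;
  best = eps;
  for (int i = 0; i < n; ++i) {
    double h = std::fabs(vdot(nrm, vsub(pts[i], pts[i0]))) / nlen;
    if (h > best) { best = h; i3 = i; }
  }
  if (i3 < 0) return false; // coplanar input

  Vec3 interior = {
    (pts[i0].x + pts[i1].x + pts[i2].x + pts[i3].x) / 4.0,
    (pts[i0].y + pts[i1].y + pts[i2].y + pts[i3].y) / 4.0,
    (pts[i0].z + pts[i1].z + pts[i2].z + pts[i3].z) / 4.0};

  static thread_local std::vector<std::array<int, 3>> faces;
  static thread_local std::vector<std::array<double, 4>> planes;
  faces.clear();
  planes.clear();
  auto add_face = [&](int a, int b, int c) {
    std::array<double, 4> pl;
    if (!face_plane(pts[a], pts[b], pts[c], interior, pl, eps)) return;
    faces.push_back({a, b, c});
    planes.push_back(pl);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);
  if (faces.size() != 4) return false;

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  // scratch buffers reused across insertions (hot path: the polymer Monte
  // Carlo evaluates one hull per Metropolis-evaluated move)
  static thread_local std::vector<int> vis;
  static thread_local std::vector<std::array<int, 2>> edges;
  static thread_local std::vector<signed char> edge_dup;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = 1;
    vis.clear();
    for (int f = 0; f < static_cast<int>(faces.size()); ++f) {
      const auto& pl = planes[f];
      double s = pl[0] * pts[p].x + pl[1] * pts[p].y + pl[2] * pts[p].z - pl[3];
      if (s > eps) vis.push_back(f);
    }
    if (vis.empty()) continue; // inside or on the current hull: not extreme

    // horizon = undirected edges of visible faces seen exactly once
    edges.clear();
    edge_dup.clear();
    for (int f : vis) {
      const auto& fc = faces[f];
      for (int e = 0; e < 3; ++e) {
        int a = fc[e], b = fc[(e + 1) % 3];
        if (a > b) std::swap(a, b);
        bool dup = false;
        for (size_t k = 0; k < edges.size(); ++k) {
          if (edges[k][0] == a && edges[k][1] == b) {
            edge_dup[k] = 1;
            dup = true;
            break;
          }
        }
        if (!dup) {
          edges.push_back({a, b});
          edge_dup.push_back(0);
        }
      }
    }

    // drop visible faces (back to front)
    std::sort(vis.begin(), vis.end(), std::greater<int>());
    for (int f : vis) {
      faces[f] = faces.back(); faces.pop_back();
      planes[f] = planes.back(); planes.pop_back();
    }
    for (size_t k = 0; k < edges.size(); ++k)
      if (!edge_dup[k]) add_face(edges[k][0], edges[k][1], p);
  }

  // collect vertices and volume (fan from the interior point)
  hull.faces = faces;
  hull.planes = planes;
  for (const auto& fc : faces)
    for (int v : fc) hull.is_vertex[v] = 1;
  double vol = 0.0;
  for (const auto& fc : faces) {
    Vec3 a = vsub(pts[fc[0]], interior);
    Vec3 b = vsub(pts[fc[1]], interior);
    Vec3 c = vsub(pts[fc[2]], interior);
    vol += std::fabs(vdot(a, vcross(b, c))) / 6.0;
  }
  hull.volume = vol;
  hull.ok = true;
  return true;
}

bool point_in_hull(const Hull& hull, const Vec3& p, double slack) {
  for (const auto& pl : hull.planes) {
    double s = pl[0] * p.x + pl[1] * p.y + pl[2] * p.z - pl[3];
    if (s > slack) return false;
  }
  return true;
}

// Candidate vertices of A ∩ B: vertices of one hull inside the other, plus
// hull-edge × facet-plane crossing points that lie inside both. The
// intersection of two convex polytopes is the convex hull of that set.
static void edge_list(const Hull& h, std::vector<std::pair<int, int>>& edges) {
  std::map<std::pair<int, int>, char> seen;
  for (const auto& fc : h.faces)
    for (int e = 0; e < 3; ++e) {
      int a = fc[e], b = fc[(e + 1) % 3];
      if (a > b) std::swap(a, b);
      seen[{a, b}] = 1;
    }
  edges.clear();
  for (const auto& kv : seen) edges.push_back(kv.first);
}

static void collect_crossings(const std::vector<Vec3>& ptsA, const Hull& hullA,
                              const Hull& hullB, double slack,
                              std::vector<Vec3>& out) {
  std::vector<std::pair<int, int>> edges;
  edge_list(hullA, edges);
  for (const auto& e : edges) {
    const Vec3& u = ptsA[e.first];
    const Vec3& v = ptsA[e.second];
    for (const auto& pl : hullB.planes) {
      double su = pl[0] * u.x + pl[1] * u.y + pl[2] * u.z - pl[3];
      double sv = pl[0] * v.x + pl[1] * v.y + pl[2] * v.z - pl[3];
      if ((su > 0 && sv < 0) || (su < 0 && sv > 0)) {
        double t = su / (su - sv);
        Vec3 q = {u.x + t * (v.x - u.x), u.y + t * (v.y - u.y),
                  u.z + t * (v.z - u.z)};
        if (point_in_hull(hullA, q, slack) && point_in_hull(hullB, q, slack))
          out.push_back(q);
      }
    }
  }
}

double hull_intersection_volume(const std::vector<Vec3>& a,
                                const std::vector<Vec3>& b,
                                bool& exact_ok) {
  exact_ok = false;
  Hull ha, hb;
  if (!build_hull(a, ha) || !build_hull(b, hb)) return 0.0;
  double slack = 10.0 * std::max(ha.eps, hb.eps);

  std::vector<Vec3> cand;
  for (size_t i = 0; i < a.size(); ++i)
    if (ha.is_vertex[i] && point_in_hull(hb, a[i], slack)) cand.push_back(a[i]);
  for (size_t i = 0; i < b.size(); ++i)
    if (hb.is_vertex[i] && point_in_hull(ha, b[i], slack)) cand.push_back(b[i]);
  collect_crossings(a, ha, hb, slack, cand);
  collect_crossings(b, hb, ha, slack, cand);

  exact_ok = true;
  if (cand.size() < 4) return 0.0;
  Hull hi;
  if (!build_hull(cand, hi)) return 0.0; // flat intersection: measure zero
  return hi.volume;
}

} // namespace nucleome
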