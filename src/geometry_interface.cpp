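#include <Rcpp.h>
#include "hull.h"
using namespace Rcpp;
using nucleome::Vec3;
using nucleome::Hull;

static std::vector<Vec3> as_points(const NumericMatrix& m) {
  if (m.ncol() != 3) stop("point matrix must have 3 columns (x, y, z)");
  std::vector<Vec3> pts(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) pts[i] = {m(i, 0), m(i, 1), m(i, 2)};
  return pts;
}

// [[Rcpp::export]]
List cpp_convhull(NumericMatrix pts) {
  std::vector<Vec3> p = as_points(pts);
  Hull h;
  bool ok = nucleome::build_hull(p, h);
  IntegerVector verts;
  IntegerMatrix faces(0, 3);
  if (ok) {
    std::vector<int> vs;
    for (size_t i = 0; i < h.is_vertex.size(); ++i)
      if (h.is_vertex[i]) vs.push_back(static_cast<int>(i) + 1);
    verts = wrap(vs);
    faces = IntegerMatrix(h.faces.size(), 3);
    for (size_t f = 0; f < h.faces.size(); ++f)
      for (int k = 0; k < 3; ++k) faces(f, k) = h.faces[f][k] + 1;
  }
  return List::create(_["ok"] = ok, _["vertices"] = verts, _["faces"] = faces,
                      _["volume"] = h.volume);
}

// [[Rcpp::export]]
LogicalVector cpp_in_hull(NumericMatrix pts, NumericMatrix query) {
  std::vector<Vec3> p = as_points(pts);
  Hull h;
  if (!nucleome::build_hull(p, h)) stop("degenerate hull");
  std::vector<Vec3> q = as_points(query);
  LogicalVector out(q.size());
  double slack = 10.0 * h.eps;
  for (size_t i = 0; i < q.size(); ++i)
    out[i] = nucleome::point_in_hull(h, q[i], slack);
  return out;
}

// [[Rcpp::export]]
List cpp_hull_intersection_volume(NumericMatrix a, NumericMatrix b) {
  std::vector<Vec3> pa = as_points(a), pb = as_points(b);
  bool exact_ok = false;
  double v = nucleome::hull_intersection_volume(pa, pb, exact_ok);
  return List::create(_["volume"] = v, _["exact_ok"] = exact_ok);
}

// Monte Carlo fallback: uniform samples in the overlap of the two bounding
// boxes, fraction inside both hulls. Uses R's RNG stream.
// [[Rcpp::export]]
double cpp_mc_intersection_volume(NumericMatrix a, NumericMatrix b,
                                  int n_samples) {
  std::vector<Vec3> pa = as_points(a), pb = as_points(b);
  Hull ha, hb;
  if (!nucleome::build_hull(pa, ha) || !nucleome::build_hull(pb, hb))
    return 0.0;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  auto box = [&](const std::vector<Vec3>& p, double* l, double* h) {
    l[0] = l[1] = l[2] = R_PosInf; h[0] = h[1] = h[2] = R_NegInf;
    for (const Vec3& v : p) {
      l[0] = std::min(l[0], v.x); h[0] = std::max(h[0], v.x);
      l[1] = std::min(l[1], v.y); h[1] = std::max(h[1], v.y);
      l[2] = std::min(l[2], v.z); h[2] = std::max(h[2], v.z);
    }
  };
  double la[3], ua[3], lb[3], ub[3];
  box(pa, la, ua); box(pb, lb, ub);
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::max(la[d], lb[d]);
    hi[d] = std::min(ua[d], ub[d]);
    if (hi[d] <= lo[d]) return 0.0;
  }
  double vol_box = (hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]);
  double slack = 10.0 * std::max(ha.eps, hb.eps);
  int inside = 0;
  for (int i = 0; i < n_samples; ++i) {
    Vec3 q = {lo[0] + unif_rand() * (hi[0] - lo[0]),
              lo[1] + unif_rand() * (hi[1] - lo[1]),
              lo[2] + unif_rand() * (hi[2] - lo[2])};
    if (nucleome::point_in_hull(ha, q, slack) &&
        nucleome::point_in_hull(hb, q, slack))
      ++inside;
  }
  return vol_box * static_cast<double>(inside) / n_samples;
}
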