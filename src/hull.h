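#ifndef NUCLEOME_HULL_H
#define NUCLEOME_HULL_H

#include <vector>
#include <array>

namespace nucleome {

struct Vec3 {
  double x, y, z;
};

// Triangulated 3D convex hull. Planes are stored with unit outward normals:
// a point p is inside iff dot(n, p) <= d + eps for every facet.
struct Hull {
  std::vector<std::array<int, 3>> faces;    // vertex indices into the input
  std::vector<std::array<double, 4>> planes; // nx, ny, nz, d (unit normal)
  std::vector<char> is_vertex;               // per input point
  double volume = 0.0;
  double eps = 0.0;                          // scale-derived tolerance
  bool ok = false;                           // false when input is degenerate
};

bool build_hull(const std::vector<Vec3>& pts, Hull& hull);
bool point_in_hull(const Hull& hull, const Vec3& p, double slack);
double hull_intersection_volume(const std::vector<Vec3>& a,
                                const std::vector<Vec3>& b,
                                bool& exact_ok);

} // namespace nucleome

#endif
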