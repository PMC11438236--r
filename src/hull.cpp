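#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <utility>

using namespace Rcpp;

// Randomized-order incremental convex hull in 3D.
// Faces carry unnormalized outward normals; visibility is judged against a
// tolerance scaled by the bounding-box diagonal so the routine behaves the
// same for bodies measured in metres or millimetres.

namespace {

struct Face {
  int a, b, c;          // vertex indices (0-based)
  double nx, ny, nz;    // outward normal (not unit)
  double off;           // dot(n, vertex a)
  bool alive;
};

inline void face_normal(const NumericMatrix &P, Face &f) {
  double ux = P(f.b, 0) - P(f.a, 0), uy = P(f.b, 1) - P(f.a, 1), uz = P(f.b, 2) - P(f.a, 2);
  double vx = P(f.c, 0) - P(f.a, 0), vy = P(f.c, 1) - P(f.a, 1), vz = P(f.c, 2) - P(f.a, 2);
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * P(f.a, 0) + f.ny * P(f.a, 1) + f.nz * P(f.a, 2);
}

inline double plane_dist(const NumericMatrix &P, const Face &f, int i) {
  double d = f.nx * P(i, 0) + f.ny * P(i, 1) + f.nz * P(i, 2) - f.off;
  double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  return nn > 0 ? d / nn : 0.0;
}

} // namespace

// [[Rcpp::export(name = ".hull_cpp")]]
List hull_cpp(NumericMatrix P, double tol_rel = 1e-10) {
  const int n = P.nrow();
  if (P.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) return List::create(_["rank"] = (n > 1 ? 1 : 0), _["faces"] = IntegerMatrix(0, 3));

  // scale: bounding-box diagonal
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = hi[k] = P(0, k); }
  for (int i = 1; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      if (P(i, k) < lo[k]) lo[k] = P(i, k);
      if (P(i, k) > hi[k]) hi[k] = P(i, k);
    }
  double diag = 0.0;
  for (int k = 0; k < 3; ++k) diag += (hi[k] - lo[k]) * (hi[k] - lo[k]);
  diag = std::sqrt(diag);
  const double eps = std::max(tol_rel * diag, 1e-300);

  // initial simplex: farthest-point heuristic
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = 0.0;
    for (int k = 0; k < 3; ++k) d += (P(i, k) - P(i0, k)) * (P(i, k) - P(i0, k));
    if (d > best) { best = d; i1 = i; }
  }
  if (std::sqrt(best) <= eps)
    return List::create(_["rank"] = 0, _["faces"] = IntegerMatrix(0, 3));

  // farthest from line i0-i1
  best = -1.0;
  double ax = P(i1, 0) - P(i0, 0), ay = P(i1, 1) - P(i0, 1), az = P(i1, 2) - P(i0, 2);
  double alen = std::sqrt(ax * ax + ay * ay + az * az);
  for (int i = 0; i < n; ++i) {
    double bx = P(i, 0) - P(i0, 0), by = P(i, 1) - P(i0, 1), bz = P(i, 2) - P(i0, 2);
    double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    double d = std::sqrt(cx * cx + cy * cy + cz * cz) / alen;
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps)
    return List::create(_["rank"] = 1, _["faces"] = IntegerMatrix(0, 3));

  // farthest from plane i0-i1-i2
  Face base{i0, i1, i2, 0, 0, 0, 0, true};
  face_normal(P, base);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(plane_dist(P, base, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps)
    return List::create(_["rank"] = 2, _["faces"] = IntegerMatrix(0, 3));

  // interior reference point of the initial simplex
  double in_x = (P(i0, 0) + P(i1, 0) + P(i2, 0) + P(i3, 0)) / 4.0;
  double in_y = (P(i0, 1) + P(i1, 1) + P(i2, 1) + P(i3, 1)) / 4.0;
  double in_z = (P(i0, 2) + P(i1, 2) + P(i2, 2) + P(i3, 2)) / 4.0;

  std::vector<Face> faces;
  faces.reserve(256);
  auto add_face = [&](int a, int b, int c) {
    Face f{a, b, c, 0, 0, 0, 0, true};
    face_normal(P, f);
    // orient outward with respect to the interior reference point
    double d = f.nx * in_x + f.ny * in_y + f.nz * in_z - f.off;
    if (d > 0) { std::swap(f.b, f.c); face_normal(P, f); }
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    visible.clear();
    for (int fi = 0; fi < (int)faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      if (plane_dist(P, faces[fi], p) > eps) visible.push_back(fi);
    }
    if (visible.empty()) continue; // interior or on the surface

    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    edges.reserve(visible.size() * 3);
    for (int vi : visible) {
      const Face &f = faces[vi];
      edges.push_back(std::make_pair(f.a, f.b));
      edges.push_back(std::make_pair(f.b, f.c));
      edges.push_back(std::make_pair(f.c, f.a));
    }
    for (int vi : visible) faces[vi].alive = false;
    for (const auto &e : edges) {
      bool has_rev = false;
      for (const auto &e2 : edges)
        if (e2.first == e.second && e2.second == e.first) { has_rev = true; break; }
      if (!has_rev) add_face(e.first, e.second, p);
    }
  }

  int m = 0;
  for (const Face &f : faces) if (f.alive) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1; out(r, 1) = f.b + 1; out(r, 2) = f.c + 1;
    ++r;
  }
  return List::create(_["rank"] = 3, _["faces"] = out);
}
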