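// Periodic Voronoi cell volumes for orthorhombic boxes.
//
// Each site's cell is computed by half-space clipping: start from the
// site-centred Wigner-Seitz cuboid (box/2 in every direction, the bisector
// constraint against the site's own periodic images) and clip by the
// bisector plane of every other site's 27 periodic images, nearest first,
// stopping once no remaining plane can cut the current polyhedron.
// Cell volumes therefore sum exactly to the box volume.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct V3 {
  double x, y, z;
};

static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

typedef std::vector<V3> Face;
typedef std::vector<Face> Poly;

// Clip convex polyhedron to half-space dot(n, p) <= d. Returns false if the
// polyhedron vanishes.
static bool clip_poly(Poly &poly, const V3 &n, double d, double eps) {
  Poly out;
  std::vector<V3> cap;
  for (const Face &f : poly) {
    Face nf;
    size_t m = f.size();
    for (size_t i = 0; i < m; ++i) {
      const V3 &a = f[i];
      const V3 &b = f[(i + 1) % m];
      double da = dot(n, a) - d;
      double db = dot(n, b) - d;
      if (da <= eps) nf.push_back(a);
      if ((da < -eps && db > eps) || (da > eps && db < -eps)) {
        double t = da / (da - db);
        V3 p = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
                a.z + t * (b.z - a.z)};
        nf.push_back(p);
        cap.push_back(p);
      }
    }
    if (nf.size() >= 3) out.push_back(nf);
  }
  if (!cap.empty()) {
    // dedupe
    std::vector<V3> uniq;
    for (const V3 &p : cap) {
      bool seen = false;
      for (const V3 &q : uniq) {
        double dx = p.x - q.x, dy = p.y - q.y, dz = p.z - q.z;
        if (dx * dx + dy * dy + dz * dz < 1e-14) { seen = true; break; }
      }
      if (!seen) uniq.push_back(p);
    }
    if (uniq.size() >= 3) {
      // order around the plane: basis (u, v) orthogonal to n
      V3 c = {0, 0, 0};
      for (const V3 &p : uniq) { c.x += p.x; c.y += p.y; c.z += p.z; }
      c.x /= uniq.size(); c.y /= uniq.size(); c.z /= uniq.size();
      V3 ref = (std::fabs(n.x) < 0.9) ? V3{1, 0, 0} : V3{0, 1, 0};
      V3 u = {n.y * ref.z - n.z * ref.y, n.z * ref.x - n.x * ref.z,
              n.x * ref.y - n.y * ref.x};
      double ul = std::sqrt(dot(u, u));
      u.x /= ul; u.y /= ul; u.z /= ul;
      V3 v = {n.y * u.z - n.z * u.y, n.z * u.x - n.x * u.z,
              n.x * u.y - n.y * u.x};
      std::vector<std::pair<double, size_t> > ang(uniq.size());
      for (size_t i = 0; i < uniq.size(); ++i) {
        V3 r = {uniq[i].x - c.x, uniq[i].y - c.y, uniq[i].z - c.z};
        ang[i] = std::make_pair(std::atan2(dot(r, v), dot(r, u)), i);
      }
      std::sort(ang.begin(), ang.end());
      Face capf;
      for (size_t i = 0; i < ang.size(); ++i) capf.push_back(uniq[ang[i].second]);
      out.push_back(capf);
    }
  }
  poly.swap(out);
  return !poly.empty();
}

// Volume of a convex polyhedron containing the origin: sum of fan
// tetrahedra from the origin over each face (all same sign per face since
// the origin is interior; absolute value makes orientation irrelevant).
static double poly_volume(const Poly &poly) {
  double vol = 0.0;
  for (const Face &f : poly) {
    double fv = 0.0;
    const V3 &a = f[0];
    for (size_t j = 1; j + 1 < f.size(); ++j) {
      const V3 &b = f[j];
      const V3 &c = f[j + 1];
      fv += a.x * (b.y * c.z - b.z * c.y) - a.y * (b.x * c.z - b.z * c.x) +
            a.z * (b.x * c.y - b.y * c.x);
    }
    vol += std::fabs(fv) / 6.0;
  }
  return vol;
}

static double max_r2(const Poly &poly) {
  double m = 0.0;
  for (const Face &f : poly)
    for (const V3 &p : f) {
      double r2 = dot(p, p);
      if (r2 > m) m = r2;
    }
  return m;
}

struct Cand {
  double d2;
  V3 delta;
};

// [[Rcpp::export]]
NumericVector voronoi_volumes_cpp(NumericMatrix pts, NumericVector box) {
  int n = pts.nrow();
  if (n < 1) stop("need at least one site");
  double bx = box[0], by = box[1], bz = box[2];
  if (bx <= 0 || by <= 0 || bz <= 0) stop("box edges must be positive");
  std::vector<V3> p(n);
  for (int i = 0; i < n; ++i) {
    // wrap into [0, box)
    double x = pts(i, 0) - bx * std::floor(pts(i, 0) / bx);
    double y = pts(i, 1) - by * std::floor(pts(i, 1) / by);
    double z = pts(i, 2) - bz * std::floor(pts(i, 2) / bz);
    p[i] = {x, y, z};
  }
  double eps = 1e-9 * std::max(bx, std::max(by, bz));
  NumericVector vols(n);
  std::vector<Cand> cands;
  cands.reserve(27 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    cands.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx0 = p[j].x - p[i].x;
      double dy0 = p[j].y - p[i].y;
      double dz0 = p[j].z - p[i].z;
      for (int sx = -1; sx <= 1; ++sx)
        for (int sy = -1; sy <= 1; ++sy)
          for (int sz = -1; sz <= 1; ++sz) {
            double dx = dx0 + sx * bx, dy = dy0 + sy * by, dz = dz0 + sz * bz;
            if (std::fabs(dx) > bx || std::fabs(dy) > by || std::fabs(dz) > bz)
              continue;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < 1e-12) {
              stop("coincident sites: atoms %d and %d (periodic image)",
                   i + 1, j + 1);
            }
            // plane can cut the WS cuboid only if the bisector distance is
            // below the cuboid's farthest extent along delta
            double reach = (std::fabs(dx) * bx + std::fabs(dy) * by +
                            std::fabs(dz) * bz);
            if (d2 < reach) {
              Cand c;
              c.d2 = d2;
              c.delta = {dx, dy, dz};
              cands.push_back(c);
            }
          }
    }
    std::sort(cands.begin(), cands.end(),
              [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });
    // initial Wigner-Seitz cuboid, site at origin
    double hx = bx / 2, hy = by / 2, hz = bz / 2;
    V3 v000 = {-hx, -hy, -hz}, v100 = {hx, -hy, -hz};
    V3 v010 = {-hx, hy, -hz}, v110 = {hx, hy, -hz};
    V3 v001 = {-hx, -hy, hz}, v101 = {hx, -hy, hz};
    V3 v011 = {-hx, hy, hz}, v111 = {hx, hy, hz};
    Poly poly;
    poly.push_back(Face{v000, v010, v110, v100}); // z = -hz
    poly.push_back(Face{v001, v101, v111, v011}); // z = +hz
    poly.push_back(Face{v000, v100, v101, v001}); // y = -hy
    poly.push_back(Face{v010, v011, v111, v110}); // y = +hy
    poly.push_back(Face{v000, v001, v011, v010}); // x = -hx
    poly.push_back(Face{v100, v110, v111, v101}); // x = +hx
    double mr2 = max_r2(poly);
    for (const Cand &c : cands) {
      if (c.d2 / 4.0 >= mr2) break;
      if (!clip_poly(poly, c.delta, c.d2 / 2.0, eps)) {
        stop("Voronoi cell of atom %d vanished (degenerate geometry)", i + 1);
      }
      mr2 = max_r2(poly);
    }
    vols[i] = poly_volume(poly);
  }
  return vols;
}
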