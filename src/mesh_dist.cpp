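#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5 (barycentric region tests; exact up to rounding).
static inline void closest_point_triangle(const double *p,
                                          const double *a, const double *b,
                                          const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double sqdist(const double *p, const double *q) {
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

struct TriSoup {
  std::vector<double> va, vb, vc;  // flattened triangle corners
  int n;
};

static TriSoup make_soup(const NumericMatrix &V, const IntegerMatrix &F) {
  TriSoup s;
  s.n = F.nrow();
  s.va.resize(3 * s.n); s.vb.resize(3 * s.n); s.vc.resize(3 * s.n);
  for (int t = 0; t < s.n; ++t) {
    int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    for (int k = 0; k < 3; ++k) {
      s.va[3 * t + k] = V(ia, k);
      s.vb[3 * t + k] = V(ib, k);
      s.vc[3 * t + k] = V(ic, k);
    }
  }
  return s;
}

// Uniform grid over triangle bounding boxes; queries expand cell shells
// outward until the untouched region provably lies farther than the best
// hit, so results are identical to brute force.
struct TriGrid {
  double lo[3], cs;
  int dim[3];
  std::vector<std::vector<int> > cells;

  int cell_index(int ix, int iy, int iz) const {
    return (iz * dim[1] + iy) * dim[0] + ix;
  }
  void locate(const double *p, int *c) const {
    for (int k = 0; k < 3; ++k) {
      int i = (int)std::floor((p[k] - lo[k]) / cs);
      c[k] = std::max(0, std::min(dim[k] - 1, i));
    }
  }
};

static TriGrid build_grid(const TriSoup &s) {
  TriGrid g;
  double hi[3];
  for (int k = 0; k < 3; ++k) {
    g.lo[k] = std::numeric_limits<double>::infinity();
    hi[k] = -std::numeric_limits<double>::infinity();
  }
  for (int t = 0; t < s.n; ++t) {
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(s.va[3 * t + k], std::min(s.vb[3 * t + k], s.vc[3 * t + k]));
      double mx = std::max(s.va[3 * t + k], std::max(s.vb[3 * t + k], s.vc[3 * t + k]));
      g.lo[k] = std::min(g.lo[k], mn);
      hi[k] = std::max(hi[k], mx);
    }
  }
  double ext = 0.0;
  for (int k = 0; k < 3; ++k) ext = std::max(ext, hi[k] - g.lo[k]);
  if (ext <= 0.0) ext = 1.0;
  int target = (int)std::ceil(std::cbrt((double)std::max(1, s.n)));
  target = std::max(1, std::min(64, target));
  g.cs = ext / target * 1.000001;  // slight inflation keeps hi inside the grid
  for (int k = 0; k < 3; ++k) {
    g.dim[k] = std::max(1, (int)std::ceil((hi[k] - g.lo[k]) / g.cs));
  }
  g.cells.assign((size_t)g.dim[0] * g.dim[1] * g.dim[2], std::vector<int>());
  for (int t = 0; t < s.n; ++t) {
    int clo[3], chi[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(s.va[3 * t + k], std::min(s.vb[3 * t + k], s.vc[3 * t + k]));
      double mx = std::max(s.va[3 * t + k], std::max(s.vb[3 * t + k], s.vc[3 * t + k]));
      clo[k] = std::max(0, std::min(g.dim[k] - 1, (int)std::floor((mn - g.lo[k]) / g.cs)));
      chi[k] = std::max(0, std::min(g.dim[k] - 1, (int)std::floor((mx - g.lo[k]) / g.cs)));
    }
    for (int iz = clo[2]; iz <= chi[2]; ++iz)
      for (int iy = clo[1]; iy <= chi[1]; ++iy)
        for (int ix = clo[0]; ix <= chi[0]; ++ix)
          g.cells[g.cell_index(ix, iy, iz)].push_back(t);
  }
  return g;
}

// Distance from p to the slab of cells already searched (Chebyshev radius r
// around the home cell, clipped to the grid). Triangles outside it are at
// least this far away.
static double processed_bound(const TriGrid &g, const double *p,
                              const int *home, int r) {
  double bound = std::numeric_limits<double>::infinity();
  for (int k = 0; k < 3; ++k) {
    int lo_c = home[k] - r, hi_c = home[k] + r;
    if (lo_c > 0) {  // cells exist below the processed slab on axis k
      double face = g.lo[k] + lo_c * g.cs;
      bound = std::min(bound, p[k] - face);
    }
    if (hi_c < g.dim[k] - 1) {
      double face = g.lo[k] + (hi_c + 1) * g.cs;
      bound = std::min(bound, face - p[k]);
    }
  }
  return std::max(0.0, bound);
}

// [[Rcpp::export]]
List cpp_mesh_dist(NumericMatrix points, NumericMatrix V, IntegerMatrix F,
                   bool use_index = true) {
  const int np = points.nrow();
  TriSoup s = make_soup(V, F);
  NumericVector dist(np);
  IntegerVector face(np);
  NumericMatrix closest(np, 3);
  std::vector<int> stamp(s.n, -1);

  TriGrid grid;
  if (use_index) grid = build_grid(s);

  double p[3], cp[3], best_cp[3];
  for (int i = 0; i < np; ++i) {
    p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int best_t = -1;
    if (!use_index) {
      for (int t = 0; t < s.n; ++t) {
        closest_point_triangle(p, &s.va[3 * t], &s.vb[3 * t], &s.vc[3 * t], cp);
        double d2 = sqdist(p, cp);
        if (d2 < best) { best = d2; best_t = t; best_cp[0] = cp[0]; best_cp[1] = cp[1]; best_cp[2] = cp[2]; }
      }
    } else {
      int home[3];
      grid.locate(p, home);
      int rmax = 0;
      for (int k = 0; k < 3; ++k)
        rmax = std::max(rmax, std::max(home[k], grid.dim[k] - 1 - home[k]));
      for (int r = 0; r <= rmax; ++r) {
        // shell of cells at Chebyshev distance exactly r
        for (int dz = -r; dz <= r; ++dz) {
          int iz = home[2] + dz;
          if (iz < 0 || iz >= grid.dim[2]) continue;
          for (int dy = -r; dy <= r; ++dy) {
            int iy = home[1] + dy;
            if (iy < 0 || iy >= grid.dim[1]) continue;
            bool on_face = (std::abs(dz) == r) || (std::abs(dy) == r);
            int step = on_face ? 1 : (r == 0 ? 1 : 2 * r);
            for (int dx = -r; dx <= r; dx += step) {
              int ix = home[0] + dx;
              if (ix < 0 || ix >= grid.dim[0]) continue;
              const std::vector<int> &bucket =
                  grid.cells[grid.cell_index(ix, iy, iz)];
              for (size_t bi = 0; bi < bucket.size(); ++bi) {
                int t = bucket[bi];
                if (stamp[t] == i) continue;
                stamp[t] = i;
                closest_point_triangle(p, &s.va[3 * t], &s.vb[3 * t],
                                       &s.vc[3 * t], cp);
                double d2 = sqdist(p, cp);
                if (d2 < best ||
                    (d2 == best && best_t >= 0 && t < best_t)) {
                  best = d2; best_t = t;
                  best_cp[0] = cp[0]; best_cp[1] = cp[1]; best_cp[2] = cp[2];
                }
              }
            }
          }
        }
        double bnd = processed_bound(grid, p, home, r);
        if (best_t >= 0 && std::sqrt(best) <= bnd) break;
      }
    }
    dist[i] = std::sqrt(best);
    face[i] = best_t;  // 0-based; R side shifts
    closest(i, 0) = best_cp[0]; closest(i, 1) = best_cp[1]; closest(i, 2) = best_cp[2];
  }
  return List::create(_["dist"] = dist, _["face"] = face,
                      _["closest"] = closest);
}

// Nearest mesh vertex per query point; ties broken by lowest vertex index.
// [[Rcpp::export]]
IntegerVector cpp_nearest_vertex(NumericMatrix points, NumericMatrix V) {
  const int np = points.nrow(), nv = V.nrow();
  IntegerVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    double best = std::numeric_limits<double>::infinity();
    int best_v = -1;
    for (int v = 0; v < nv; ++v) {
      double q[3] = { V(v, 0), V(v, 1), V(v, 2) };
      double d2 = sqdist(p, q);
      if (d2 < best) { best = d2; best_v = v; }
    }
    out[i] = best_v;
  }
  return out;
}
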