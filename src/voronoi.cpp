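#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Voronoi cell areas clipped to a rectangle, without constructing the global
// tessellation: each cell is the intersection of the rectangle with the
// half-planes bounded by the perpendicular bisectors towards the other sites.
// A uniform grid supplies neighbor candidates in roughly increasing distance;
// a site q can only cut the current cell of p when |q - p| < 2 * (maximum
// distance from p to a cell vertex), which bounds the search.

struct Pt { double x, y; };

static double polygon_area(const std::vector<Pt>& poly) {
  const size_t m = poly.size();
  if (m < 3) return 0.0;
  double a = 0.0;
  for (size_t k = 0; k < m; ++k) {
    const Pt& u = poly[k];
    const Pt& v = poly[(k + 1) % m];
    a += u.x * v.y - v.x * u.y;
  }
  return std::fabs(a) / 2.0;
}

// clip polygon to the half-plane of points closer to p than to q
static void clip_halfplane(std::vector<Pt>& poly, double px, double py,
                           double qx, double qy, std::vector<Pt>& tmp) {
  const size_t m = poly.size();
  if (m == 0) return;
  const double ax = px - qx, ay = py - qy;           // normal towards p
  const double mx = (px + qx) / 2.0, my = (py + qy) / 2.0;
  const double c = ax * mx + ay * my;                // keep: ax*x + ay*y >= c
  tmp.clear();
  for (size_t k = 0; k < m; ++k) {
    const Pt& u = poly[k];
    const Pt& v = poly[(k + 1) % m];
    const double fu = ax * u.x + ay * u.y - c;
    const double fv = ax * v.x + ay * v.y - c;
    if (fu >= 0) {
      tmp.push_back(u);
      if (fv < 0) {
        double t = fu / (fu - fv);
        tmp.push_back({u.x + t * (v.x - u.x), u.y + t * (v.y - u.y)});
      }
    } else if (fv >= 0) {
      double t = fu / (fu - fv);
      tmp.push_back({u.x + t * (v.x - u.x), u.y + t * (v.y - u.y)});
    }
  }
  poly.swap(tmp);
}

// [[Rcpp::export]]
NumericVector voronoi_areas_cpp(NumericVector x, NumericVector y,
                                double xmin, double xmax,
                                double ymin, double ymax) {
  const int n = x.size();
  NumericVector areas(n);
  const double W = xmax - xmin, H = ymax - ymin;
  if (n == 1) { areas[0] = W * H; return areas; }

  // uniform grid with ~1 site per cell
  const double cs = std::sqrt(W * H / (double)n);
  const int gx = std::max(1, (int)std::ceil(W / cs));
  const int gy = std::max(1, (int)std::ceil(H / cs));
  const double csx = W / gx, csy = H / gy;
  std::vector<std::vector<int>> bins((size_t)gx * gy);
  std::vector<int> cxi(n), cyi(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((x[i] - xmin) / csx);
    int cy = (int)std::floor((y[i] - ymin) / csy);
    cx = std::min(std::max(cx, 0), gx - 1);
    cy = std::min(std::max(cy, 0), gy - 1);
    cxi[i] = cx; cyi[i] = cy;
    bins[(size_t)cy * gx + cx].push_back(i);
  }
  const double cmin = std::min(csx, csy);
  const int rmax = std::max(gx, gy);

  std::vector<Pt> poly, tmp;
  std::vector<std::pair<double, int>> cand;
  for (int i = 0; i < n; ++i) {
    poly.assign({{xmin, ymin}, {xmax, ymin}, {xmax, ymax}, {xmin, ymax}});
    double maxd2 = 0.0;
    for (const Pt& v : poly) {
      double dx = v.x - x[i], dy = v.y - y[i];
      maxd2 = std::max(maxd2, dx * dx + dy * dy);
    }
    for (int r = 0; r <= rmax; ++r) {
      if (r > 0) {
        // any site in ring r or beyond is at least (r - 1) * cmin away
        double dmin = (r - 1) * cmin;
        if (dmin * dmin > 4.0 * maxd2) break;
      }
      cand.clear();
      const int clo_x = cxi[i] - r, chi_x = cxi[i] + r;
      const int clo_y = cyi[i] - r, chi_y = cyi[i] + r;
      for (int cy = std::max(clo_y, 0); cy <= std::min(chi_y, gy - 1); ++cy) {
        for (int cx = std::max(clo_x, 0); cx <= std::min(chi_x, gx - 1); ++cx) {
          if (r > 0 && cx != clo_x && cx != chi_x && cy != clo_y && cy != chi_y)
            continue;  // interior of the ring: already visited
          for (int j : bins[(size_t)cy * gx + cx]) {
            if (j == i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i];
            cand.push_back({dx * dx + dy * dy, j});
          }
        }
      }
      std::sort(cand.begin(), cand.end());
      for (const auto& cd : cand) {
        if (cd.first == 0.0) continue;      // exact duplicate: cannot bisect
        if (cd.first >= 4.0 * maxd2) break; // too far to cut the cell
        clip_halfplane(poly, x[i], y[i], x[cd.second], y[cd.second], tmp);
        if (poly.size() < 3) break;
        maxd2 = 0.0;
        for (const Pt& v : poly) {
          double dx = v.x - x[i], dy = v.y - y[i];
          maxd2 = std::max(maxd2, dx * dx + dy * dy);
        }
      }
      if (poly.size() < 3) break;
    }
    areas[i] = polygon_area(poly);
  }
  return areas;
}
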