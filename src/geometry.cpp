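#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Convex hulls (Andrew monotone chain), shoelace areas, boundary-inclusive
// point-in-convex-polygon tests, and exact union area of convex polygons
// via a vertical slab decomposition.
//
// Hullsets are passed flattened: concatenated CCW vertex arrays `vx`, `vy`
// and a 0-based offset vector `off` of length n_hulls + 1.
// ---------------------------------------------------------------------------

struct Pt {
  double x, y;
  bool operator<(const Pt& o) const {
    return x < o.x || (x == o.x && y < o.y);
  }
  bool operator==(const Pt& o) const { return x == o.x && y == o.y; }
};

static inline double cross3(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// Monotone chain on deduplicated points; returns CCW hull without repeating
// the first vertex. Collinear sets collapse to their 2 extreme points;
// coincident sets to 1 point.
static std::vector<Pt> monotone_chain(std::vector<Pt> pts) {
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  const int n = (int)pts.size();
  if (n <= 2) return pts;
  std::vector<Pt> h(2 * n);
  int m = 0;
  for (int i = 0; i < n; ++i) {            // lower hull
    while (m >= 2 && cross3(h[m - 2], h[m - 1], pts[i]) <= 0) --m;
    h[m++] = pts[i];
  }
  for (int i = n - 2, lo = m + 1; i >= 0; --i) {  // upper hull
    while (m >= lo && cross3(h[m - 2], h[m - 1], pts[i]) <= 0) --m;
    h[m++] = pts[i];
  }
  h.resize(m - 1);
  return h;
}

static double shoelace(const std::vector<Pt>& v) {
  const int n = (int)v.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += v[j].x * v[i].y - v[i].x * v[j].y;
  return 0.5 * a;  // CCW => positive
}

// Boundary-inclusive containment with a relative tolerance so that a point
// equal to a vertex, or lying on an edge, counts as inside.
static bool in_hull(const double* hx, const double* hy, int m,
                    double px, double py) {
  if (m == 1) {
    return std::fabs(px - hx[0]) <= 1e-9 * (1.0 + std::fabs(hx[0])) &&
           std::fabs(py - hy[0]) <= 1e-9 * (1.0 + std::fabs(hy[0]));
  }
  if (m == 2) {  // degenerate segment
    const double ax = hx[1] - hx[0], ay = hy[1] - hy[0];
    const double bx = px - hx[0],  by = py - hy[0];
    const double cr = ax * by - ay * bx;
    const double scale = std::sqrt(ax * ax + ay * ay) *
                         (std::sqrt(bx * bx + by * by) + 1.0) + 1.0;
    if (std::fabs(cr) > 1e-9 * scale) return false;
    const double dot = ax * bx + ay * by, len2 = ax * ax + ay * ay;
    return dot >= -1e-9 * scale && dot <= len2 + 1e-9 * scale;
  }
  for (int i = 0, j = m - 1; i < m; j = i++) {
    const double ex = hx[i] - hx[j], ey = hy[i] - hy[j];
    const double qx = px - hx[j],  qy = py - hy[j];
    const double cr = ex * qy - ey * qx;
    const double scale = (std::fabs(ex) + std::fabs(ey)) *
                         (std::fabs(qx) + std::fabs(qy)) + 1.0;
    if (cr < -1e-9 * scale) return false;  // strictly right of a CCW edge
  }
  return true;
}

// Build one hull per row of `members` (1-based indices into x/y).
// Returns flattened hull vertices plus areas, degeneracy flags and bboxes.
// [[Rcpp::export]]
List cpp_build_hulls(NumericVector x, NumericVector y, IntegerMatrix members) {
  const int nh = members.nrow(), k = members.ncol();
  std::vector<double> vx, vy;
  IntegerVector off(nh + 1);
  NumericVector areas(nh);
  LogicalVector degen(nh);
  NumericMatrix bbox(nh, 4);  // xmin, xmax, ymin, ymax
  off[0] = 0;
  std::vector<Pt> pts;
  for (int h = 0; h < nh; ++h) {
    pts.clear();
    for (int j = 0; j < k; ++j) {
      const int idx = members(h, j) - 1;
      Pt p; p.x = x[idx]; p.y = y[idx];
      pts.push_back(p);
    }
    std::vector<Pt> hull = monotone_chain(pts);
    const double a = shoelace(hull);
    areas[h] = a;
    degen[h] = (hull.size() < 3 || a <= 0.0);
    double xmin = hull[0].x, xmax = hull[0].x, ymin = hull[0].y, ymax = hull[0].y;
    for (size_t i = 0; i < hull.size(); ++i) {
      vx.push_back(hull[i].x); vy.push_back(hull[i].y);
      xmin = std::min(xmin, hull[i].x); xmax = std::max(xmax, hull[i].x);
      ymin = std::min(ymin, hull[i].y); ymax = std::max(ymax, hull[i].y);
    }
    bbox(h, 0) = xmin; bbox(h, 1) = xmax; bbox(h, 2) = ymin; bbox(h, 3) = ymax;
    off[h + 1] = (int)vx.size();
  }
  return List::create(_["vx"] = NumericVector(vx.begin(), vx.end()),
                      _["vy"] = NumericVector(vy.begin(), vy.end()),
                      _["offsets"] = off,
                      _["areas"] = areas,
                      _["degenerate"] = degen,
                      _["bbox"] = bbox);
}

// Number of hulls containing each query point (boundary-inclusive), the
// g_{i,j} counts of the cross-validation score. Bounding boxes prefilter.
// [[Rcpp::export]]
IntegerVector cpp_count_containing(NumericVector vx, NumericVector vy,
                                   IntegerVector off, NumericMatrix bbox,
                                   NumericVector px, NumericVector py) {
  const int nh = off.size() - 1, np = px.size();
  IntegerVector g(np);
  for (int i = 0; i < np; ++i) {
    const double qx = px[i], qy = py[i];
    const double tx = 1e-9 * (1.0 + std::fabs(qx));
    const double ty = 1e-9 * (1.0 + std::fabs(qy));
    int cnt = 0;
    for (int h = 0; h < nh; ++h) {
      if (qx < bbox(h, 0) - tx || qx > bbox(h, 1) + tx ||
          qy < bbox(h, 2) - ty || qy > bbox(h, 3) + ty) continue;
      const int s = off[h], m = off[h + 1] - s;
      if (in_hull(&vx[s], &vy[s], m, qx, qy)) ++cnt;
    }
    g[i] = cnt;
  }
  return g;
}

// Indices (1-based) of query points enclosed by each hull.
// [[Rcpp::export]]
List cpp_enclosed(NumericVector vx, NumericVector vy, IntegerVector off,
                  NumericMatrix bbox, NumericVector px, NumericVector py) {
  const int nh = off.size() - 1, np = px.size();
  List out(nh);
  std::vector<int> buf;
  for (int h = 0; h < nh; ++h) {
    buf.clear();
    const int s = off[h], m = off[h + 1] - s;
    for (int i = 0; i < np; ++i) {
      const double qx = px[i], qy = py[i];
      const double tx = 1e-9 * (1.0 + std::fabs(qx));
      const double ty = 1e-9 * (1.0 + std::fabs(qy));
      if (qx < bbox(h, 0) - tx || qx > bbox(h, 1) + tx ||
          qy < bbox(h, 2) - ty || qy > bbox(h, 3) + ty) continue;
      if (in_hull(&vx[s], &vy[s], m, qx, qy)) buf.push_back(i + 1);
    }
    out[h] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact union area of a set of convex polygons.
//
// Vertical slab decomposition: slab boundaries are all vertex x-coordinates
// plus the x-coordinates of all pairwise edge crossings. Within a slab no
// interval endpoints cross, so the union length of the y-intervals is linear
// in x and the slab's contribution is width * length(mid). Degenerate
// (area-0) polygons contribute nothing.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_union_area(NumericVector vx, NumericVector vy, IntegerVector off) {
  const int nh = off.size() - 1;
  struct Seg { double x1, y1, x2, y2; int poly; };
  std::vector<Seg> segs;
  std::vector<double> xs;
  std::vector<double> pxmin(nh, 0), pxmax(nh, 0);
  for (int h = 0; h < nh; ++h) {
    const int s = off[h], m = off[h + 1] - off[h];
    if (m < 3) continue;
    double xmn = vx[s], xmx = vx[s];
    for (int i = 0; i < m; ++i) {
      const int j = (i + 1) % m;
      Seg sg; sg.x1 = vx[s + i]; sg.y1 = vy[s + i];
      sg.x2 = vx[s + j]; sg.y2 = vy[s + j]; sg.poly = h;
      segs.push_back(sg);
      xs.push_back(vx[s + i]);
      xmn = std::min(xmn, vx[s + i]); xmx = std::max(xmx, vx[s + i]);
    }
    pxmin[h] = xmn; pxmax[h] = xmx;
  }
  if (segs.empty()) return 0.0;

  // pairwise crossings between edges of different polygons
  const int ns = (int)segs.size();
  for (int a = 0; a < ns; ++a) {
    const Seg& A = segs[a];
    const double axmin = std::min(A.x1, A.x2), axmax = std::max(A.x1, A.x2);
    const double aymin = std::min(A.y1, A.y2), aymax = std::max(A.y1, A.y2);
    for (int b = a + 1; b < ns; ++b) {
      const Seg& B = segs[b];
      if (A.poly == B.poly) continue;
      if (std::max(B.x1, B.x2) < axmin || std::min(B.x1, B.x2) > axmax ||
          std::max(B.y1, B.y2) < aymin || std::min(B.y1, B.y2) > aymax)
        continue;
      const double rx = A.x2 - A.x1, ry = A.y2 - A.y1;
      const double sx = B.x2 - B.x1, sy = B.y2 - B.y1;
      const double den = rx * sy - ry * sx;
      if (den == 0.0) continue;  // parallel; endpoints already breakpoints
      const double qx = B.x1 - A.x1, qy = B.y1 - A.y1;
      const double tA = (qx * sy - qy * sx) / den;
      const double tB = (qx * ry - qy * rx) / den;
      if (tA >= 0.0 && tA <= 1.0 && tB >= 0.0 && tB <= 1.0)
        xs.push_back(A.x1 + tA * rx);
    }
  }

  std::sort(xs.begin(), xs.end());
  xs.erase(std::unique(xs.begin(), xs.end()), xs.end());

  std::vector<std::pair<double, double> > iv;
  double area = 0.0;
  for (size_t b = 0; b + 1 < xs.size(); ++b) {
    const double x1 = xs[b], x2 = xs[b + 1], w = x2 - x1;
    if (w <= 0.0) continue;
    const double xm = 0.5 * (x1 + x2);
    iv.clear();
    for (int h = 0; h < nh; ++h) {
      const int s = off[h], m = off[h + 1] - off[h];
      if (m < 3 || xm <= pxmin[h] || xm >= pxmax[h]) continue;
      double ylo = R_PosInf, yhi = R_NegInf;
      for (int i = 0; i < m; ++i) {
        const int j = (i + 1) % m;
        const double xa = vx[s + i], xb = vx[s + j];
        if ((xa < xm && xb > xm) || (xa > xm && xb < xm)) {
          const double yv = vy[s + i] +
            (vy[s + j] - vy[s + i]) * (xm - xa) / (xb - xa);
          ylo = std::min(ylo, yv); yhi = std::max(yhi, yv);
        }
      }
      if (yhi > ylo) iv.push_back(std::make_pair(ylo, yhi));
    }
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    double L = 0.0, lo = iv[0].first, hi = iv[0].second;
    for (size_t i = 1; i < iv.size(); ++i) {
      if (iv[i].first > hi) { L += hi - lo; lo = iv[i].first; hi = iv[i].second; }
      else hi = std::max(hi, iv[i].second);
    }
    L += hi - lo;
    area += w * L;
  }
  return area;
}
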