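// Per-frame convex-hull geometry for the feature stage: body/head hull
// areas and the body-hull intersection area, computed for every frame of a
// two-animal track in one pass.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Pt { double x, y; };

static inline double cross(const Pt &o, const Pt &a, const Pt &b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// Andrew monotone chain; returns hull in counter-clockwise order.
// Fewer than 3 distinct points -> hull of size < 3 (degenerate).
static std::vector<Pt> convex_hull(std::vector<Pt> pts) {
  std::sort(pts.begin(), pts.end(), [](const Pt &a, const Pt &b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt &a, const Pt &b) {
    return a.x == b.x && a.y == b.y;
  }), pts.end());
  int n = pts.size();
  if (n < 3) return pts;
  std::vector<Pt> h(2 * n);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  for (int i = n - 2, t = k + 1; i >= 0; --i) {
    while (k >= t && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

static double poly_area(const std::vector<Pt> &p) {
  int n = p.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    s += p[i].x * p[j].y - p[j].x * p[i].y;
  }
  return std::fabs(s) / 2.0;
}

// Sutherland-Hodgman clip of convex subject by convex clip (both CCW)
static std::vector<Pt> clip_convex_cpp(const std::vector<Pt> &subject,
                                       const std::vector<Pt> &clip) {
  std::vector<Pt> out = subject;
  int nc = clip.size();
  for (int i = 0; i < nc && out.size() > 2; ++i) {
    const Pt &a = clip[i];
    const Pt &b = clip[(i + 1) % nc];
    double ex = b.x - a.x, ey = b.y - a.y;
    std::vector<Pt> nxt;
    nxt.reserve(out.size() + 2);
    int np = out.size();
    for (int j = 0; j < np; ++j) {
      const Pt &p = out[j];
      const Pt &q = out[(j + 1) % np];
      bool pin = ex * (p.y - a.y) - ey * (p.x - a.x) >= -1e-12;
      bool qin = ex * (q.y - a.y) - ey * (q.x - a.x) >= -1e-12;
      if (pin != qin) {
        double dx = q.x - p.x, dy = q.y - p.y;
        double denom = dx * ey - dy * ex;
        double t = denom != 0.0 ?
          ((a.x - p.x) * ey - (a.y - p.y) * ex) / denom : 0.0;
        nxt.push_back({p.x + t * dx, p.y + t * dy});
      }
      if (qin) nxt.push_back(q);
    }
    out = nxt;
  }
  if (out.size() < 3) out.clear();
  return out;
}

static std::vector<Pt> row_pts(const NumericMatrix &x, const NumericMatrix &y,
                               int i) {
  std::vector<Pt> p(x.ncol());
  for (int j = 0; j < x.ncol(); ++j) p[j] = {x(i, j), y(i, j)};
  return p;
}

// [[Rcpp::export(name = ".frame_hull_geometry")]]
NumericMatrix frame_hull_geometry(NumericMatrix body_xa, NumericMatrix body_ya,
                                  NumericMatrix body_xb, NumericMatrix body_yb,
                                  NumericMatrix head_xa, NumericMatrix head_ya,
                                  NumericMatrix head_xb, NumericMatrix head_yb) {
  int n = body_xa.nrow();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create(
    "body_area_A", "body_area_B", "head_area_A", "head_area_B",
    "intersection_area");
  for (int i = 0; i < n; ++i) {
    std::vector<Pt> ha = convex_hull(row_pts(body_xa, body_ya, i));
    std::vector<Pt> hb = convex_hull(row_pts(body_xb, body_yb, i));
    out(i, 0) = poly_area(ha);
    out(i, 1) = poly_area(hb);
    out(i, 2) = poly_area(convex_hull(row_pts(head_xa, head_ya, i)));
    out(i, 3) = poly_area(convex_hull(row_pts(head_xb, head_yb, i)));
    out(i, 4) = (ha.size() > 2 && hb.size() > 2) ?
      poly_area(clip_convex_cpp(ha, hb)) : 0.0;
  }
  return out;
}
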