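// Nearest-neighbour queries used throughout the pipeline.
//
// Two primitives: (1) a 3-D kd-tree over point sites (triangle centroids or
// particle positions), matching the k-dimensional-tree procedure the field's
// morphometrics tooling uses; (2) exact point-to-triangle-surface distance
// (Ericson's closest-point-on-triangle), a full scan over faces.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

class KDTree3 {
public:
  explicit KDTree3(const NumericMatrix& pts)
    : n_(pts.nrow()), pts_(&pts[0]), idx_(static_cast<size_t>(n_)) {
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    if (n_ > 1) build(0, n_, 0);
  }

  // nearest site index (ties -> smallest index) and squared distance
  void nearest(const double* q, int& best, double& bestd2) const {
    best = -1;
    bestd2 = R_PosInf;
    search(q, 0, n_, 0, best, bestd2);
  }

private:
  int n_;
  const double* pts_;        // column-major n x 3
  std::vector<int> idx_;

  double coord(int i, int ax) const { return pts_[i + ax * n_]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = lo + (hi - lo) / 2;
    int ax = depth % 3;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void search(const double* q, int lo, int hi, int depth,
              int& best, double& bestd2) const {
    if (lo >= hi) return;
    int mid = lo + (hi - lo) / 2;
    int ax = depth % 3;
    int i = idx_[mid];
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = q[k] - coord(i, k);
      d2 += d * d;
    }
    if (d2 < bestd2 || (d2 == bestd2 && i < best)) {
      bestd2 = d2;
      best = i;
    }
    double diff = q[ax] - coord(i, ax);
    if (diff < 0) {
      search(q, lo, mid, depth + 1, best, bestd2);
      if (diff * diff <= bestd2) search(q, mid + 1, hi, depth + 1, best, bestd2);
    } else {
      search(q, mid + 1, hi, depth + 1, best, bestd2);
      if (diff * diff <= bestd2) search(q, lo, mid, depth + 1, best, bestd2);
    }
  }
};

// closest point on triangle (a, b, c) to p; Ericson, Real-Time Collision Detection
inline void closest_pt_triangle(const double* p, const double* a, const double* b,
                                const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }

  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }

  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

} // namespace

// [[Rcpp::export]]
List cpp_nearest_point(NumericMatrix query, NumericMatrix sites) {
  if (sites.nrow() == 0) stop("no sites to query against");
  KDTree3 tree(sites);
  int n = query.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    int best; double d2;
    tree.nearest(q, best, d2);
    idx[i] = best + 1;
    dist[i] = std::sqrt(d2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export]]
List cpp_nearest_triangle_exact(NumericMatrix points, NumericMatrix vertices,
                                IntegerMatrix faces) {
  int n = points.nrow(), m = faces.nrow();
  if (m == 0) stop("mesh has no faces");
  IntegerVector idx(n);
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  double p[3], a[3], b[3], c[3], cp[3], bestcp[3];
  for (int i = 0; i < n; ++i) {
    p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
    double bestd2 = R_PosInf;
    int best = -1;
    for (int f = 0; f < m; ++f) {
      int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
      for (int k = 0; k < 3; ++k) {
        a[k] = vertices(ia, k);
        b[k] = vertices(ib, k);
        c[k] = vertices(ic, k);
      }
      closest_pt_triangle(p, a, b, c, cp);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = p[k] - cp[k];
        d2 += d * d;
      }
      if (d2 < bestd2) {
        bestd2 = d2;
        best = f;
        for (int k = 0; k < 3; ++k) bestcp[k] = cp[k];
      }
    }
    idx[i] = best + 1;
    dist[i] = std::sqrt(bestd2);
    for (int k = 0; k < 3; ++k) closest(i, k) = bestcp[k];
  }
  return List::create(_["index"] = idx, _["distance"] = dist,
                      _["closest"] = closest);
}
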