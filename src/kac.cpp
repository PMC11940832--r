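// Hot loop of the divisive clusterer: for one cluster, scan every
// candidate line (all unordered pairs of member points), partition the
// members by the orientation rule (on-line points to the closed side 1,
// matching side_of_line() in R), and return the split with the largest
// area reduction. Hulls are built by a monotone chain over a single
// pre-sorted order, so each candidate costs O(m).

#include <Rcpp.h>
#include <algorithm>
#include <cfloat>
#include <numeric>
#include <vector>

using namespace Rcpp;

// shoelace area of the convex hull of points given in lexicographic
// (x, then y) order
static double hull_area_sorted(const std::vector<double>& px,
                               const std::vector<double>& py) {
  const int n = static_cast<int>(px.size());
  if (n < 3) return 0.0;
  std::vector<int> h(2 * n + 1);
  int k = 0;
  for (int i = 0; i < n; ++i) {  // lower chain
    while (k >= 2) {
      double cr = (px[h[k - 1]] - px[h[k - 2]]) * (py[i] - py[h[k - 2]]) -
                  (py[h[k - 1]] - py[h[k - 2]]) * (px[i] - px[h[k - 2]]);
      if (cr <= 0.0) --k; else break;
    }
    h[k++] = i;
  }
  const int lower = k + 1;
  for (int i = n - 2; i >= 0; --i) {  // upper chain
    while (k >= lower) {
      double cr = (px[h[k - 1]] - px[h[k - 2]]) * (py[i] - py[h[k - 2]]) -
                  (py[h[k - 1]] - py[h[k - 2]]) * (px[i] - px[h[k - 2]]);
      if (cr <= 0.0) --k; else break;
    }
    h[k++] = i;
  }
  const int m = k - 1;  // closed ring h[0..m-1], h[m] == h[0]
  if (m < 3) return 0.0;
  double s = 0.0;
  for (int i = 0; i < m; ++i)
    s += px[h[i]] * py[h[i + 1]] - py[h[i]] * px[h[i + 1]];
  return std::fabs(s) / 2.0;
}

// [[Rcpp::export]]
List kac_best_split_scan(NumericVector x, NumericVector y, IntegerVector ids,
                         double parent_area, double tol) {
  const int m = x.size();
  List none = List::create(Named("found") = false);
  if (m < 2) return none;

  std::vector<int> ord(m);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  double best_delta = -1.0;
  int best_i = -1, best_j = -1, best_minside = -1;
  int best_lo = 0, best_hi = 0;
  std::vector<char> side1(m), best_side1(m);
  std::vector<double> s1x, s1y, s2x, s2y;
  s1x.reserve(m); s1y.reserve(m); s2x.reserve(m); s2y.reserve(m);
  const double eps = 1e-12 * std::max(1.0, parent_area);
  const double neg_tol = -1e-9 * std::max(parent_area, DBL_EPSILON);

  for (int i = 0; i < m - 1; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double ax = x[i], ay = y[i], bx = x[j], by = y[j];
      if (ax == bx && ay == by) continue;  // coincident points: no line
      if (ax > bx || (ax == bx && ay > by)) {  // canonical orientation
        std::swap(ax, bx);
        std::swap(ay, by);
      }
      const double ux = bx - ax, uy = by - ay;
      int n2 = 0;
      s1x.clear(); s1y.clear(); s2x.clear(); s2y.clear();
      for (int t = 0; t < m; ++t) {
        const int k = ord[t];
        const double cr = ux * (y[k] - ay) - uy * (x[k] - ax);
        if (cr <= tol) {
          side1[k] = 1;
          s1x.push_back(x[k]); s1y.push_back(y[k]);
        } else {
          side1[k] = 0;
          s2x.push_back(x[k]); s2y.push_back(y[k]);
          ++n2;
        }
      }
      if (n2 == 0) continue;  // the >= rule kept every point on side 1

      const double a1 = hull_area_sorted(s1x, s1y);
      const double a2 = hull_area_sorted(s2x, s2y);
      double delta = parent_area - a1 - a2;
      if (delta < 0.0) {
        if (delta < neg_tol)
          stop("negative area reduction beyond tolerance: geometry error");
        delta = 0.0;
      }

      const int minside = std::min(m - n2, n2);
      const int lo = std::min(ids[i], ids[j]);
      const int hi = std::max(ids[i], ids[j]);
      bool take = false;
      if (best_i < 0 || delta > best_delta + eps) {
        take = true;
      } else if (delta >= best_delta - eps) {
        if (minside > best_minside) take = true;
        else if (minside == best_minside &&
                 (lo < best_lo || (lo == best_lo && hi < best_hi)))
          take = true;
      }
      if (take) {
        best_delta = delta;
        best_i = i; best_j = j;
        best_minside = minside;
        best_lo = lo; best_hi = hi;
        best_side1 = side1;
      }
    }
  }

  if (best_i < 0) return none;
  LogicalVector out_side(m);
  for (int k = 0; k < m; ++k) out_side[k] = best_side1[k] == 1;
  return List::create(Named("found") = true,
                      Named("a_idx") = ids[best_i],
                      Named("b_idx") = ids[best_j],
                      Named("delta") = best_delta,
                      Named("side1") = out_side);
}
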