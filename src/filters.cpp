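#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median matching stats::median (mean of the two middle order statistics
// for even counts); windows are truncated at the detector boundary, so even
// counts do occur near corners.
static double median_of(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector cube, int nrow, int ncol,
                                int npts, int k) {
  const int h = k / 2;
  NumericVector out(cube.size());
  std::vector<double> win;
  win.reserve(k * k);
  for (int p = 0; p < npts; ++p) {
    const double *ch = &cube[(R_xlen_t)p * nrow * ncol];
    double *oc = &out[(R_xlen_t)p * nrow * ncol];
    for (int c = 0; c < ncol; ++c) {
      const int c0 = std::max(0, c - h), c1 = std::min(ncol - 1, c + h);
      for (int r = 0; r < nrow; ++r) {
        const int r0 = std::max(0, r - h), r1 = std::min(nrow - 1, r + h);
        win.clear();
        for (int cc = c0; cc <= c1; ++cc)
          for (int rr = r0; rr <= r1; ++rr)
            win.push_back(ch[rr + cc * nrow]);
        oc[r + c * nrow] = median_of(win);
      }
    }
  }
  return out;
}

// Replace dead pixels by the mean spectrum of their non-dead neighbours in
// the k x k window (truncated at the boundary). Pixels whose whole window
// is dead are left unchanged and reported back.
// [[Rcpp::export]]
List cpp_fill_dead(NumericVector cube, int nrow, int ncol, int npts,
                   LogicalVector dead, int k) {
  const int h = k / 2;
  NumericVector out = clone(cube);
  std::vector<int> unfilled;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      const int idx = r + c * nrow;
      if (!dead[idx]) continue;
      const int r0 = std::max(0, r - h), r1 = std::min(nrow - 1, r + h);
      const int c0 = std::max(0, c - h), c1 = std::min(ncol - 1, c + h);
      std::vector<int> nb;
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr) {
          const int j = rr + cc * nrow;
          if (!dead[j]) nb.push_back(j);
        }
      if (nb.empty()) { unfilled.push_back(idx + 1); continue; }
      for (int p = 0; p < npts; ++p) {
        const R_xlen_t off = (R_xlen_t)p * nrow * ncol;
        double s = 0.0;
        for (size_t q = 0; q < nb.size(); ++q) s += cube[off + nb[q]];
        out[off + idx] = s / nb.size();
      }
    }
  }
  return List::create(_["cube"] = out, _["unfilled"] = wrap(unfilled));
}

static inline double cross(double ox, double oy, double ax, double ay,
                           double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// Rubber-band baseline per spectrum: support points are the spectrum minima
// inside each anchor window; between consecutive support points the
// baseline follows the lower convex hull of the spectrum (monotone-chain),
// interpolated linearly. x must be strictly ascending; anchor windows are
// given as 0-based [lo, hi] index ranges, ascending in x.
// [[Rcpp::export]]
NumericMatrix cpp_rubberband(NumericMatrix spec, NumericVector x,
                             IntegerVector win_lo, IntegerVector win_hi) {
  const int n_pix = spec.nrow(), n_pts = spec.ncol();
  const int n_anchor = win_lo.size();
  NumericMatrix base(n_pix, n_pts);
  std::vector<int> support, hull;
  support.reserve(n_anchor);
  hull.reserve(n_pts);
  for (int i = 0; i < n_pix; ++i) {
    // snap each anchor to the in-window minimum
    support.clear();
    for (int a = 0; a < n_anchor; ++a) {
      int best = win_lo[a];
      double bv = spec(i, best);
      for (int j = win_lo[a] + 1; j <= win_hi[a]; ++j)
        if (spec(i, j) < bv) { bv = spec(i, j); best = j; }
      support.push_back(best);
    }
    std::sort(support.begin(), support.end());
    support.erase(std::unique(support.begin(), support.end()), support.end());
    const int n_sup = (int)support.size();
    // lower convex hull within each inter-anchor segment, vertices pooled
    hull.clear();
    for (int a = 0; a + 1 < n_sup; ++a) {
      const int lo = support[a], hi = support[a + 1];
      size_t seg_start = hull.size();
      for (int j = lo; j <= hi; ++j) {
        while (hull.size() >= seg_start + 2) {
          const int p1 = hull[hull.size() - 2], p2 = hull[hull.size() - 1];
          if (cross(x[p1], spec(i, p1), x[p2], spec(i, p2),
                    x[j], spec(i, j)) <= 0.0)
            hull.pop_back();
          else
            break;
        }
        hull.push_back(j);
      }
      if (a + 2 < n_sup) hull.pop_back();  // next segment re-adds it
    }
    if (n_sup == 1) hull.push_back(support[0]);
    // piecewise-linear interpolation through hull vertices; constant
    // extension outside the outer support points
    int seg = 0;
    const int nh = hull.size();
    for (int j = 0; j < n_pts; ++j) {
      if (j <= hull[0]) { base(i, j) = spec(i, hull[0]); continue; }
      if (j >= hull[nh - 1]) { base(i, j) = spec(i, hull[nh - 1]); continue; }
      while (hull[seg + 1] < j) ++seg;
      const int a0 = hull[seg], a1 = hull[seg + 1];
      const double t = (x[j] - x[a0]) / (x[a1] - x[a0]);
      base(i, j) = (1.0 - t) * spec(i, a0) + t * spec(i, a1);
    }
  }
  return base;
}
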