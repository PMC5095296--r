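// Hartigan's dip statistic computed directly from its definition: the
// smallest sup-norm distance between the empirical cdf and some unimodal cdf
// (convex below the mode, concave above it, with an atom allowed at the
// mode). For a candidate distance d the sup-norm tube around the ecdf induces
// per-knot value bands; a convex (concave) branch exists inside the bands iff
// the greatest convex minorant of the upper bounds stays above the lower
// bounds (iff the least concave majorant of the lower bounds stays below the
// upper bounds). Feasibility is monotone in the mode position for each
// branch, so each check is a binary search, and the dip itself is found by
// bisection on d.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

static const double EPS = 1e-12;

// does a convex function exist with lo[i] <= f(xs[i]) <= hi[i]?
static bool convex_band_ok(const std::vector<double>& xs,
                           const std::vector<double>& lo,
                           const std::vector<double>& hi) {
  int k = (int)xs.size();
  if (k == 0) return true;
  for (int i = 0; i < k; ++i) if (lo[i] > hi[i] + EPS) return false;
  if (k <= 2) return true;
  // lower convex hull of the upper bounds (= greatest convex minorant)
  std::vector<int> h;
  h.reserve(k);
  for (int i = 0; i < k; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      if ((hi[b] - hi[a]) * (xs[i] - xs[b]) >=
          (hi[i] - hi[b]) * (xs[b] - xs[a]))
        h.pop_back();
      else break;
    }
    h.push_back(i);
  }
  int seg = 0;
  for (int i = 0; i < k; ++i) {
    while (seg + 1 < (int)h.size() - 1 && xs[h[seg + 1]] < xs[i]) ++seg;
    int a = h[seg], b = h[seg + 1];
    double v = (i == a) ? hi[a]
      : hi[a] + (hi[b] - hi[a]) * (xs[i] - xs[a]) / (xs[b] - xs[a]);
    if (v < lo[i] - EPS) return false;
  }
  return true;
}

// does a concave function exist with lo[i] <= f(xs[i]) <= hi[i]?
static bool concave_band_ok(const std::vector<double>& xs,
                            const std::vector<double>& lo,
                            const std::vector<double>& hi) {
  int k = (int)xs.size();
  if (k == 0) return true;
  for (int i = 0; i < k; ++i) if (lo[i] > hi[i] + EPS) return false;
  if (k <= 2) return true;
  // upper concave hull of the lower bounds (= least concave majorant)
  std::vector<int> h;
  h.reserve(k);
  for (int i = 0; i < k; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      if ((lo[b] - lo[a]) * (xs[i] - xs[b]) <=
          (lo[i] - lo[b]) * (xs[b] - xs[a]))
        h.pop_back();
      else break;
    }
    h.push_back(i);
  }
  int seg = 0;
  for (int i = 0; i < k; ++i) {
    while (seg + 1 < (int)h.size() - 1 && xs[h[seg + 1]] < xs[i]) ++seg;
    int a = h[seg], b = h[seg + 1];
    double v = (i == a) ? lo[a]
      : lo[a] + (lo[b] - lo[a]) * (xs[i] - xs[a]) / (xs[b] - xs[a]);
    if (v > hi[i] + EPS) return false;
  }
  return true;
}

struct Knots {
  std::vector<double> x;      // unique sorted values
  std::vector<double> Fcur;   // ecdf at the knot
  std::vector<double> Fprev;  // ecdf just below the knot
};

// mode at knot j: convex branch over knots 0..j, relaxed lower bound at j
static bool left_at_knot(const Knots& K, int j, double d) {
  std::vector<double> xs(j + 1), lo(j + 1), hi(j + 1);
  for (int i = 0; i < j; ++i) {
    xs[i] = K.x[i];
    lo[i] = std::max(0.0, K.Fcur[i] - d);
    hi[i] = K.Fprev[i] + d;
  }
  xs[j] = K.x[j];
  lo[j] = std::max(0.0, K.Fprev[j] - d);
  hi[j] = K.Fprev[j] + d;
  return convex_band_ok(xs, lo, hi);
}

// mode at knot j: concave branch over knots j..m-1, jump allowed at j
static bool right_at_knot(const Knots& K, int j, double d) {
  int m = (int)K.x.size(), k = m - j;
  std::vector<double> xs(k), lo(k), hi(k);
  xs[0] = K.x[j];
  lo[0] = std::max(0.0, K.Fcur[j] - d);
  hi[0] = std::min(1.0, K.Fcur[j] + d);
  for (int i = j + 1; i < m; ++i) {
    xs[i - j] = K.x[i];
    lo[i - j] = std::max(0.0, K.Fcur[i] - d);
    hi[i - j] = std::min(1.0, K.Fprev[i] + d);
  }
  return concave_band_ok(xs, lo, hi);
}

// mode inside the gap below knot s: convex branch over knots 0..s-1 plus a
// ceiling at x[s] (the branch may keep rising inside the gap but must stay
// inside the gap's tube before the jump at the mode)
static bool left_in_gap(const Knots& K, int s, double d) {
  std::vector<double> xs(s + 1), lo(s + 1), hi(s + 1);
  for (int i = 0; i < s; ++i) {
    xs[i] = K.x[i];
    lo[i] = std::max(0.0, K.Fcur[i] - d);
    hi[i] = K.Fprev[i] + d;
  }
  xs[s] = K.x[s];
  lo[s] = 0.0;
  hi[s] = K.Fprev[s] + d;
  return convex_band_ok(xs, lo, hi);
}

// mode inside the gap below knot s: concave branch over knots s..m-1 with
// standard bands (the branch is continuous at x[s])
static bool right_in_gap(const Knots& K, int s, double d) {
  int m = (int)K.x.size(), k = m - s;
  std::vector<double> xs(k), lo(k), hi(k);
  for (int i = s; i < m; ++i) {
    xs[i - s] = K.x[i];
    lo[i - s] = std::max(0.0, K.Fcur[i] - d);
    hi[i - s] = std::min(1.0, K.Fprev[i] + d);
  }
  return concave_band_ok(xs, lo, hi);
}

static bool feasible(const Knots& K, double d) {
  int m = (int)K.x.size();
  // mode-at-knot variant: left feasibility is monotone decreasing in j,
  // right feasibility monotone increasing; feasible iff they overlap
  int lo_j = 0, hi_j = m - 1;               // max j with left_at_knot
  while (lo_j < hi_j) {
    int mid = (lo_j + hi_j + 1) / 2;
    if (left_at_knot(K, mid, d)) lo_j = mid; else hi_j = mid - 1;
  }
  int jl = lo_j;
  lo_j = 0; hi_j = m - 1;                   // min j with right_at_knot
  while (lo_j < hi_j) {
    int mid = (lo_j + hi_j) / 2;
    if (right_at_knot(K, mid, d)) hi_j = mid; else lo_j = mid + 1;
  }
  if (lo_j <= jl && right_at_knot(K, lo_j, d) && left_at_knot(K, jl, d))
    return true;
  // mode-in-gap variant
  lo_j = 0; hi_j = m - 1;                   // max s with left_in_gap
  while (lo_j < hi_j) {
    int mid = (lo_j + hi_j + 1) / 2;
    if (left_in_gap(K, mid, d)) lo_j = mid; else hi_j = mid - 1;
  }
  int sl = lo_j;
  lo_j = 0; hi_j = m;                       // min s with right_in_gap (m = none)
  while (lo_j < hi_j) {
    int mid = (lo_j + hi_j) / 2;
    if (mid < m && right_in_gap(K, mid, d)) hi_j = mid; else lo_j = mid + 1;
  }
  return lo_j < m && lo_j <= sl &&
    right_in_gap(K, lo_j, d) && left_in_gap(K, sl, d);
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x_sorted) {
  int n = x_sorted.size();
  if (n < 2) return 0.0;
  Knots K;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x_sorted[j + 1] == x_sorted[i]) ++j;
    K.x.push_back(x_sorted[i]);
    K.Fprev.push_back((double)i / n);
    K.Fcur.push_back((double)(j + 1) / n);
    i = j + 1;
  }
  if (K.x.size() < 2) return 0.0;
  double lo = 0.0, hi = 0.26;
  while (!feasible(K, hi)) hi *= 2.0;  // safety; dip is bounded by 1/4
  while (hi - lo > 1e-11) {
    double mid = 0.5 * (lo + hi);
    if (feasible(K, mid)) hi = mid; else lo = mid;
  }
  return hi;
}
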