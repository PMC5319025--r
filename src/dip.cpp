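// Hartigan dip statistic via band feasibility.
//
// dip(F_n) = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|, where
// "unimodal" means convex on (-inf, mode], concave on [mode, inf), with a
// jump permitted only at the mode.  For a given tolerance eps the
// existence of such a G inside the band F_n +/- eps reduces to point
// constraints at the (tie-collapsed) sample values: at a non-modal value
// w_t carrying cumulative mass F_t (left limit F_{t-1}), continuity of G
// forces  F_t - eps <= G(w_t) <= F_{t-1} + eps,  and a convex
// (resp. concave) function through such vertical intervals exists iff the
// lower convex hull of the upper bounds dominates the lower bounds
// (resp. mirrored).  Feasibility is monotone both in eps and in the
// prefix/suffix length, so the dip is found by bisection on eps with a
// binary search for the longest feasible convex prefix and earliest
// feasible concave suffix.  A mode placed on a sample atom relaxes that
// single point's constraints (the jump absorbs its mass); the junction
// between the two branches is checked with the interval bounds.

#include <Rcpp.h>
using namespace Rcpp;

// Does a nondecreasing convex function exist passing through
// [lo_i, hi_i] at x_i (x strictly increasing)?  Exists iff the lower
// convex hull of (x_i, hi_i) is >= lo_i everywhere.
static bool feasible_convex(const std::vector<double>& x,
                            const std::vector<double>& lo,
                            const std::vector<double>& hi,
                            int k) {
  const double tol = 1e-12;
  if (k <= 0) return true;
  for (int i = 0; i < k; ++i)
    if (lo[i] > hi[i] + tol) return false;
  if (k == 1) return true;
  // lower convex hull of the upper bounds
  std::vector<int> h;
  h.reserve(k);
  for (int i = 0; i < k; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      // keep slopes strictly increasing: pop b if it lies on/above chord a->i
      double cross = (x[b] - x[a]) * (hi[i] - hi[a]) -
                     (x[i] - x[a]) * (hi[b] - hi[a]);
      if (cross <= 0.0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  // evaluate hull at every point, compare with lower bounds
  size_t seg = 0;
  for (int i = 0; i < k; ++i) {
    while (seg + 1 < h.size() && x[h[seg + 1]] <= x[i]) ++seg;
    double v;
    if (seg + 1 >= h.size()) {
      v = hi[h[seg]];
    } else {
      int a = h[seg], b = h[seg + 1];
      double w = (x[i] - x[a]) / (x[b] - x[a]);
      v = hi[a] + w * (hi[b] - hi[a]);
    }
    if (v < lo[i] - tol) return false;
  }
  return true;
}

struct DipData {
  std::vector<double> w;   // unique sorted values
  std::vector<double> F;   // empirical CDF at w (F[0] unused sentinel 0)
  int m;
  double n;
};

// Convex-branch feasibility over points 1..k (standard intervals),
// optionally with an extra relaxed terminal at point k+1 (left limit of a
// modal atom).
static bool conv_prefix(const DipData& d, double eps, int k,
                        bool modal_terminal) {
  int len = k + (modal_terminal ? 1 : 0);
  if (len == 0) return true;
  std::vector<double> x(len), lo(len), hi(len);
  for (int t = 1; t <= k; ++t) {
    x[t - 1] = d.w[t - 1];
    lo[t - 1] = d.F[t] - eps;        // value just right of w_t
    hi[t - 1] = d.F[t - 1] + eps;    // left limit at w_t
  }
  if (modal_terminal) {
    int t = k + 1;
    x[len - 1] = d.w[t - 1];
    lo[len - 1] = d.F[t - 1] - eps;  // left limit of G at the modal atom
    hi[len - 1] = d.F[t - 1] + eps;
  }
  return feasible_convex(x, lo, hi, len);
}

// Concave-branch feasibility over points j..m, optionally with a relaxed
// initial point at j-1 (right value of a modal atom).  Mirrored through
// (x, y) -> (-x, -y) which maps nondecreasing concave to nondecreasing
// convex.
static bool conc_suffix(const DipData& d, double eps, int j,
                        bool modal_initial) {
  int len = (d.m - j + 1) + (modal_initial ? 1 : 0);
  if (len <= 0) return true;
  std::vector<double> x(len), lo(len), hi(len);
  int idx = 0;
  for (int t = d.m; t >= j; --t, ++idx) {
    x[idx] = -d.w[t - 1];
    lo[idx] = -(d.F[t - 1] + eps);
    hi[idx] = -(d.F[t] - eps);
  }
  if (modal_initial) {
    int t = j - 1;
    x[idx] = -d.w[t - 1];
    lo[idx] = -(d.F[t] + eps);       // right value of G at the modal atom
    hi[idx] = -(d.F[t] - eps);
  }
  return feasible_convex(x, lo, hi, len);
}

static bool dip_feasible(const DipData& d, double eps) {
  int m = d.m;
  if (m <= 1) return true;
  // longest feasible convex prefix K (monotone in k)
  int lo = 0, hi = m;
  if (!conv_prefix(d, eps, 0, false)) return false;  // vacuous, never fires
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (conv_prefix(d, eps, mid, false)) lo = mid; else hi = mid - 1;
  }
  int K = lo;
  // earliest feasible concave suffix J (monotone in j)
  lo = 1; hi = m + 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (conc_suffix(d, eps, mid, false)) hi = mid; else lo = mid + 1;
  }
  int J = lo;
  if (J <= K + 1) return true;          // mode in a gap between atoms
  if (J == K + 2) {
    // single blocking atom at t = K + 1: put the mode on it
    int t = K + 1;
    if (!conv_prefix(d, eps, t - 1, true)) return false;
    if (!conc_suffix(d, eps, t + 1, true)) return false;
    // junction: left limit a <= right value b, using interval bounds
    double a_lo = d.F[t - 1] - eps;
    for (int i = 1; i < t; ++i) a_lo = std::max(a_lo, d.F[i] - eps);
    double b_hi = d.F[t] + eps;
    for (int j2 = t + 1; j2 <= m; ++j2)
      b_hi = std::min(b_hi, d.F[j2 - 1] + eps);
    return a_lo <= b_hi + 1e-12;
  }
  return false;
}

// [[Rcpp::export]]
double cpp_dip(NumericVector xs) {
  // xs must be sorted ascending, finite
  int n = xs.size();
  if (n <= 1) return 0.0;
  DipData d;
  d.n = n;
  d.w.reserve(n);
  std::vector<double> cnt;
  for (int i = 0; i < n; ++i) {
    if (d.w.empty() || xs[i] > d.w.back()) {
      d.w.push_back(xs[i]);
      cnt.push_back(1.0);
    } else {
      cnt.back() += 1.0;
    }
  }
  d.m = d.w.size();
  if (d.m == 1) return 0.0;
  d.F.resize(d.m + 1);
  d.F[0] = 0.0;
  for (int t = 1; t <= d.m; ++t) d.F[t] = d.F[t - 1] + cnt[t - 1] / d.n;
  double lo = 0.0, hi = 0.25;
  if (dip_feasible(d, lo)) return 0.0;
  for (int it = 0; it < 40; ++it) {
    double mid = 0.5 * (lo + hi);
    if (dip_feasible(d, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}
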