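#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximal absolute pooled-variance t statistic over all circular arcs of x.
// An arc [i..j] (0-based, inclusive) is compared against its complement;
// eligible arcs have width >= min_width and every non-empty complement piece
// >= min_width (so a split never creates a fragment shorter than min_width).
// Zero pooled variance with distinct means yields +Inf (perfect split).
static void max_arc_t(const std::vector<double> &x, int min_width,
                      int &best_i, int &best_j, double &best_t) {
  const int n = (int)x.size();
  best_i = -1; best_j = -1; best_t = -1.0;
  if (n < 2 * min_width) return;
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int p = 0; p < n; ++p) {
    S[p + 1] = S[p] + x[p];
    S2[p + 1] = S2[p] + x[p] * x[p];
  }
  const double tot = S[n], tot2 = S2[n];
  // relative floor below which a pooled variance counts as exactly zero
  // (guards fp cancellation so perfect splits tie at +Inf reproducibly)
  const double var_floor = 1e-10 * (tot2 / n + 1e-300);
  const double diff_floor = 1e-6 * std::sqrt(tot2 / n + 1e-300);
  for (int i = 0; i < n; ++i) {
    if (i != 0 && i < min_width) continue;          // left piece too short
    for (int j = i + min_width - 1; j < n; ++j) {
      int wa = j - i + 1, wc = n - wa;
      if (wc < min_width) break;
      if (j != n - 1 && n - 1 - j < min_width) continue;  // right piece short
      double sa = S[j + 1] - S[i], sa2 = S2[j + 1] - S2[i];
      double ma = sa / wa, mc = (tot - sa) / wc;
      double ssa = sa2 - wa * ma * ma;
      double ssc = (tot2 - sa2) - wc * mc * mc;
      if (ssa < 0) ssa = 0;
      if (ssc < 0) ssc = 0;
      double sp2 = (ssa + ssc) / (n - 2);
      double diff = std::fabs(ma - mc);
      double t;
      if (sp2 <= var_floor) {
        t = diff > diff_floor ? R_PosInf : 0.0;
      } else {
        t = diff / std::sqrt(sp2 * (1.0 / wa + 1.0 / wc));
      }
      if (t > best_t) { best_t = t; best_i = i; best_j = j; }
    }
  }
}

// [[Rcpp::export]]
List cbs_max_arc_cpp(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  // center for numerical shift-invariance of the t statistic
  double m = 0;
  for (double e : v) m += e;
  m /= v.size();
  for (double &e : v) e -= m;
  int i, j;
  double t;
  max_arc_t(v, min_width, i, j, t);
  return List::create(_["i"] = i, _["j"] = j, _["t"] = t);
}

// Permutation test for the observed max arc t. Counts strict exceedances
// (t_perm > t_obs); ties at the observed maximum do not count against the
// split. Stops early once the exceedance count already forces p >= alpha.
// Uses R's RNG so set.seed() upstream controls the shuffles.
// [[Rcpp::export]]
List cbs_perm_test_cpp(NumericVector x, double t_obs, int n_perm,
                       int min_width, double alpha) {
  std::vector<double> v(x.begin(), x.end());
  double m = 0;
  for (double e : v) m += e;
  m /= v.size();
  for (double &e : v) e -= m;

  const double stop_at = alpha * n_perm;  // exceed >= stop_at => p >= alpha
  int exceed = 0, done = 0;
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle with R's RNG
    for (int k = (int)v.size() - 1; k > 0; --k) {
      int idx = (int)std::floor(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(v[k], v[idx]);
    }
    int i, j;
    double t;
    max_arc_t(v, min_width, i, j, t);
    if (t > t_obs) ++exceed;
    ++done;
    if (exceed >= stop_at) break;
  }
  bool significant = (done == n_perm) && (exceed < stop_at);
  return List::create(_["exceed"] = exceed, _["n_done"] = done,
                      _["p_value"] = (double)exceed / done,
                      _["significant"] = significant);
}
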