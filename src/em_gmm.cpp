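#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG_2PI = 1.837877066409345483560659472811;

// log density of a bivariate normal with covariance [[a,b],[b,d]]
static inline double ldbvn(double x0, double x1, double m0, double m1,
                           double a, double b, double d) {
  double det = a * d - b * b;
  double e0 = x0 - m0, e1 = x1 - m1;
  double q = (d * e0 * e0 - 2.0 * b * e0 * e1 + a * e1 * e1) / det;
  return -LOG_2PI - 0.5 * std::log(det) - 0.5 * q;
}

// ensure positive-definiteness by inflating the diagonal
static inline void regularize(double &a, double &b, double &d, double ridge) {
  a += ridge;
  d += ridge;
  int guard = 0;
  while (a * d - b * b <= 1e-300 && guard++ < 60) {
    a += ridge > 0 ? ridge : 1e-12;
    d += ridge > 0 ? ridge : 1e-12;
    b *= 0.5;
  }
}

// EM for a K-component full-covariance bivariate Gaussian mixture on
// weighted points. X: N x 2 data, wt: point multiplicities (duplicate
// feature values are collapsed upstream; the likelihood equals the full
// unweighted data likelihood), mu0: K x 2 initial means. Returns fitted
// parameters, hard assignments (1-based), the log-likelihood trace and
// final value.
// Optional w0 (length K) and cov0 (2x2xK, flattened) warm-start the
// weights and covariances; empty vectors fall back to uniform weights and
// the pooled data covariance diagonal.
// [[Rcpp::export]]
List em_gmm_cpp(NumericMatrix X, NumericVector wt, NumericMatrix mu0,
                NumericVector w0, NumericVector cov0,
                int max_iter, double tol, double ridge) {
  const int N = X.nrow(), K = mu0.nrow();
  if (N < 1 || K < 1) stop("empty input to EM");
  double W = 0;
  for (int n = 0; n < N; ++n) W += wt[n];

  std::vector<double> w(K, 1.0 / K);
  std::vector<double> m0(K), m1(K), ca(K), cb(K), cd(K);
  // initial covariances: data variance (shared), ridge-regularized
  double s0 = 0, s1 = 0, v0 = 0, v1 = 0;
  for (int n = 0; n < N; ++n) { s0 += wt[n] * X(n, 0); s1 += wt[n] * X(n, 1); }
  s0 /= W; s1 /= W;
  for (int n = 0; n < N; ++n) {
    v0 += wt[n] * (X(n, 0) - s0) * (X(n, 0) - s0);
    v1 += wt[n] * (X(n, 1) - s1) * (X(n, 1) - s1);
  }
  v0 = v0 / W + ridge; v1 = v1 / W + ridge;
  if (v0 <= 0) v0 = 1e-6;
  if (v1 <= 0) v1 = 1e-6;
  const bool have_w0 = w0.size() == K, have_c0 = cov0.size() == 4 * K;
  for (int k = 0; k < K; ++k) {
    m0[k] = mu0(k, 0); m1[k] = mu0(k, 1);
    if (have_w0) w[k] = w0[k];
    if (have_c0) {
      ca[k] = cov0[4 * k + 0]; cb[k] = cov0[4 * k + 1]; cd[k] = cov0[4 * k + 3];
      regularize(ca[k], cb[k], cd[k], ridge);
    } else {
      ca[k] = v0; cb[k] = 0.0; cd[k] = v1;
    }
  }

  NumericMatrix resp(N, K);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll_prev = R_NegInf, ll = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // E-step with log-sum-exp
    ll = 0.0;
    for (int n = 0; n < N; ++n) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double lw = w[k] > 0 ? std::log(w[k]) : -700.0;
        double lp = lw + ldbvn(X(n, 0), X(n, 1), m0[k], m1[k],
                               ca[k], cb[k], cd[k]);
        resp(n, k) = lp;
        if (lp > mx) mx = lp;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(resp(n, k) - mx);
      double lse = mx + std::log(s);
      ll += wt[n] * lse;
      for (int k = 0; k < K; ++k) resp(n, k) = std::exp(resp(n, k) - lse);
    }
    trace.push_back(ll);
    if (iter > 0 && std::fabs(ll - ll_prev) < tol * (1.0 + std::fabs(ll))) {
      converged = true;
      break;
    }
    ll_prev = ll;

    // M-step
    for (int k = 0; k < K; ++k) {
      double nk = 0, mm0 = 0, mm1 = 0;
      for (int n = 0; n < N; ++n) {
        double r = wt[n] * resp(n, k);
        nk += r;
        mm0 += r * X(n, 0);
        mm1 += r * X(n, 1);
      }
      if (nk < 1e-10) { w[k] = nk / W; continue; }  // keep previous mean/cov
      w[k] = nk / W;
      m0[k] = mm0 / nk; m1[k] = mm1 / nk;
      double a = 0, b = 0, d = 0;
      for (int n = 0; n < N; ++n) {
        double r = wt[n] * resp(n, k);
        double e0 = X(n, 0) - m0[k], e1 = X(n, 1) - m1[k];
        a += r * e0 * e0;
        b += r * e0 * e1;
        d += r * e1 * e1;
      }
      a /= nk; b /= nk; d /= nk;
      regularize(a, b, d, ridge);
      ca[k] = a; cb[k] = b; cd[k] = d;
    }
  }

  IntegerVector assign(N);
  for (int n = 0; n < N; ++n) {
    int best = 0;
    double bv = R_NegInf;
    for (int k = 0; k < K; ++k) {
      if (resp(n, k) > bv) { bv = resp(n, k); best = k; }
    }
    assign[n] = best + 1;
  }

  NumericMatrix means(K, 2);
  NumericVector covs(Dimension(2, 2, K));
  NumericVector weights(K);
  for (int k = 0; k < K; ++k) {
    means(k, 0) = m0[k]; means(k, 1) = m1[k];
    weights[k] = w[k];
    covs[4 * k + 0] = ca[k]; covs[4 * k + 1] = cb[k];
    covs[4 * k + 2] = cb[k]; covs[4 * k + 3] = cd[k];
  }
  return List::create(
      _["weights"] = weights, _["means"] = means, _["covariances"] = covs,
      _["loglik"] = ll, _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
      _["assignments"] = assign, _["n_iter"] = (int)trace.size(),
      _["converged"] = converged);
}

// Hard assignment of points to mixture components plus total log-likelihood.
// [[Rcpp::export]]
List gmm_assign_cpp(NumericMatrix X, NumericVector weights, NumericMatrix means,
                    NumericVector covs) {
  const int N = X.nrow(), K = means.nrow();
  IntegerVector assign(N);
  double ll = 0.0;
  for (int n = 0; n < N; ++n) {
    double mx = R_NegInf;
    int best = 0;
    double lse_acc = 0.0;
    std::vector<double> lp(K);
    for (int k = 0; k < K; ++k) {
      double lw = weights[k] > 0 ? std::log(weights[k]) : -700.0;
      lp[k] = lw + ldbvn(X(n, 0), X(n, 1), means(k, 0), means(k, 1),
                         covs[4 * k + 0], covs[4 * k + 1], covs[4 * k + 3]);
      if (lp[k] > mx) { mx = lp[k]; best = k; }
    }
    for (int k = 0; k < K; ++k) lse_acc += std::exp(lp[k] - mx);
    ll += mx + std::log(lse_acc);
    assign[n] = best + 1;
  }
  return List::create(_["assignments"] = assign, _["loglik"] = ll);
}
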