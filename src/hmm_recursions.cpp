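#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Log-space HMM recursions. All inputs are natural-log quantities:
//   log_pi : n          initial state distribution
//   log_A  : n x n      transition matrix (structural zeros are -Inf)
//   log_B  : T x n      per-sample emission log-densities
// States are 0-based internally; returned paths are 1-based for R.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logsumexp_row(const double *x, int n) {
  double m = NEG_INF;
  for (int i = 0; i < n; ++i) if (x[i] > m) m = x[i];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericVector log_pi, NumericMatrix log_A,
                              NumericMatrix log_B) {
  const int T = log_B.nrow(), n = log_B.ncol();
  NumericMatrix la(T, n), lb(T, n), gamma(T, n);
  std::vector<double> work(n);

  // forward
  for (int j = 0; j < n; ++j) la(0, j) = log_pi[j] + log_B(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) work[i] = la(t - 1, i) + log_A(i, j);
      la(t, j) = logsumexp_row(work.data(), n) + log_B(t, j);
    }
  }
  for (int j = 0; j < n; ++j) work[j] = la(T - 1, j);
  const double loglik = logsumexp_row(work.data(), n);

  // backward
  for (int j = 0; j < n; ++j) lb(T - 1, j) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j)
        work[j] = log_A(i, j) + log_B(t + 1, j) + lb(t + 1, j);
      lb(t, i) = logsumexp_row(work.data(), n);
    }
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n; ++j) work[j] = la(t, j) + lb(t, j);
    const double z = logsumexp_row(work.data(), n);
    for (int j = 0; j < n; ++j)
      gamma(t, j) = (z == NEG_INF) ? 1.0 / n : std::exp(work[j] - z);
  }

  // expected transition counts, summed over t (for Baum-Welch M-step)
  NumericMatrix xi_sum(n, n);
  for (int t = 0; t < T - 1; ++t) {
    double z = NEG_INF;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double v = la(t, i) + log_A(i, j) + log_B(t + 1, j) + lb(t + 1, j);
        if (v > z) z = v;
      }
    if (z == NEG_INF) continue;
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        s += std::exp(la(t, i) + log_A(i, j) + log_B(t + 1, j) + lb(t + 1, j) - z);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        xi_sum(i, j) += std::exp(la(t, i) + log_A(i, j) + log_B(t + 1, j) +
                                 lb(t + 1, j) - z) / s;
  }

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik, _["log_alpha"] = la);
}

// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericVector log_pi, NumericMatrix log_A,
                     NumericMatrix log_B) {
  const int T = log_B.nrow(), n = log_B.ncol();
  NumericMatrix delta(T, n);
  IntegerMatrix psi(T, n);

  for (int j = 0; j < n; ++j) delta(0, j) = log_pi[j] + log_B(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double best = NEG_INF; int arg = 0;
      for (int i = 0; i < n; ++i) {
        double v = delta(t - 1, i) + log_A(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + log_B(t, j);
      psi(t, j) = arg;
    }
  }
  double best = NEG_INF; int arg = 0;
  for (int j = 0; j < n; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }

  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R

  return List::create(_["path"] = path, _["log_joint"] = best);
}

// Fixed-lag (online) decoding: at step t the state emitted for time t - lag is
// obtained by backtracking `lag` steps from the current best partial path.
// Trailing samples (the last `lag`) are resolved from the final best path, so
// lag >= T reduces exactly to offline Viterbi.
// [[Rcpp::export]]
IntegerVector hmm_fixed_lag_viterbi_cpp(NumericVector log_pi, NumericMatrix log_A,
                                        NumericMatrix log_B, int lag) {
  const int T = log_B.nrow(), n = log_B.ncol();
  NumericMatrix delta(T, n);
  IntegerMatrix psi(T, n);
  IntegerVector out(T);

  for (int j = 0; j < n; ++j) delta(0, j) = log_pi[j] + log_B(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double best = NEG_INF; int arg = 0;
      for (int i = 0; i < n; ++i) {
        double v = delta(t - 1, i) + log_A(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + log_B(t, j);
      psi(t, j) = arg;
    }
    if (t >= lag) {
      double b = NEG_INF; int a = 0;
      for (int j = 0; j < n; ++j) if (delta(t, j) > b) { b = delta(t, j); a = j; }
      int s = a;
      for (int k = t; k > t - lag; --k) s = psi(k, s);
      out[t - lag] = s;
    }
  }
  // resolve the tail from the final best path
  double b = NEG_INF; int a = 0;
  for (int j = 0; j < n; ++j)
    if (delta(T - 1, j) > b) { b = delta(T - 1, j); a = j; }
  int s = a;
  int from = (T - 1 < lag) ? 0 : T - lag;
  for (int t = T - 1; t >= from; --t) {
    out[t] = s;
    if (t > 0) s = psi(t, s);
  }
  for (int t = 0; t < T; ++t) out[t] += 1;
  return out;
}
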