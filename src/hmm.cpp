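#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a discrete HMM with precomputed emission
// probabilities.  `emis` is n x k, `trans` k x k (row-stochastic), `init`
// length k, `starts` 1-based indices where independent sequences begin.

// [[Rcpp::export(name = ".hmm_forward_loglik")]]
double hmm_forward_loglik(NumericMatrix emis, NumericMatrix trans,
                          NumericVector init, IntegerVector starts) {
  int n = emis.nrow(), k = emis.ncol();
  std::vector<bool> is_start(n + 1, false);
  for (int s = 0; s < starts.size(); ++s) is_start[starts[s] - 1] = true;
  std::vector<double> phi(k), nphi(k);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (is_start[t]) {
      for (int j = 0; j < k; ++j) phi[j] = init[j] * emis(t, j);
    } else {
      for (int j = 0; j < k; ++j) {
        double a = 0.0;
        for (int i = 0; i < k; ++i) a += phi[i] * trans(i, j);
        nphi[j] = a * emis(t, j);
      }
      phi = nphi;
    }
    double c = 0.0;
    for (int j = 0; j < k; ++j) c += phi[j];
    if (c <= 0.0 || !R_finite(c)) return R_NegInf;
    for (int j = 0; j < k; ++j) phi[j] /= c;
    ll += std::log(c);
  }
  return ll;
}

// Predictive state probabilities P(S_t = j | obs_{1..t-1}) for
// one-step-ahead pseudo-residuals; returns an n x k matrix.

// [[Rcpp::export(name = ".hmm_predictive")]]
NumericMatrix hmm_predictive(NumericMatrix emis, NumericMatrix trans,
                             NumericVector init, IntegerVector starts) {
  int n = emis.nrow(), k = emis.ncol();
  std::vector<bool> is_start(n + 1, false);
  for (int s = 0; s < starts.size(); ++s) is_start[starts[s] - 1] = true;
  NumericMatrix pred(n, k);
  std::vector<double> phi(k), nphi(k);
  for (int t = 0; t < n; ++t) {
    if (is_start[t]) {
      for (int j = 0; j < k; ++j) pred(t, j) = init[j];
    } else {
      for (int j = 0; j < k; ++j) {
        double a = 0.0;
        for (int i = 0; i < k; ++i) a += phi[i] * trans(i, j);
        pred(t, j) = a;
      }
    }
    double c = 0.0;
    for (int j = 0; j < k; ++j) { nphi[j] = pred(t, j) * emis(t, j); c += nphi[j]; }
    if (c <= 0.0) c = 1e-300;
    for (int j = 0; j < k; ++j) phi[j] = nphi[j] / c;
  }
  return pred;
}

// Global (Viterbi) decoding; returns 1-based state indices.

// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericMatrix emis, NumericMatrix trans,
                          NumericVector init, IntegerVector starts) {
  int n = emis.nrow(), k = emis.ncol();
  std::vector<bool> is_start(n + 1, false);
  for (int s = 0; s < starts.size(); ++s) is_start[starts[s] - 1] = true;
  NumericMatrix delta(n, k);
  IntegerMatrix psi(n, k);
  const double NEG = -1e300;
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double le = emis(t, j) > 0 ? std::log(emis(t, j)) : NEG;
      if (is_start[t]) {
        delta(t, j) = std::log(init[j]) + le;
        psi(t, j) = -1;
      } else {
        double best = NEG * 2; int arg = 0;
        for (int i = 0; i < k; ++i) {
          double v = delta(t - 1, i) + std::log(trans(i, j));
          if (v > best) { best = v; arg = i; }
        }
        delta(t, j) = best + le;
        psi(t, j) = arg;
      }
    }
  }
  IntegerVector path(n);
  // trace back each independent sequence separately
  int t_end = n - 1;
  while (t_end >= 0) {
    int t_begin = t_end;
    while (!is_start[t_begin]) --t_begin;
    int arg = 0; double best = delta(t_end, 0);
    for (int j = 1; j < k; ++j)
      if (delta(t_end, j) > best) { best = delta(t_end, j); arg = j; }
    path[t_end] = arg + 1;
    for (int t = t_end; t > t_begin; --t) {
      arg = psi(t, arg);
      path[t - 1] = arg + 1;
    }
    t_end = t_begin - 1;
  }
  return path;
}
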