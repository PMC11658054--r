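#include <Rcpp.h>
using namespace Rcpp;

// Recursions for a 2-state HMM given per-frame per-state emission
// log-densities. Scaled-probability implementations (log-sum at each step).

static inline double logsum2(double a, double b) {
  double m = a > b ? a : b;
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
double hmm_forward_loglik(NumericMatrix logdens, NumericMatrix logGamma,
                          NumericVector logdelta) {
  int n = logdens.nrow();
  double a0 = logdelta[0] + logdens(0, 0);
  double a1 = logdelta[1] + logdens(0, 1);
  for (int t = 1; t < n; ++t) {
    double b0 = logsum2(a0 + logGamma(0, 0), a1 + logGamma(1, 0)) + logdens(t, 0);
    double b1 = logsum2(a0 + logGamma(0, 1), a1 + logGamma(1, 1)) + logdens(t, 1);
    a0 = b0; a1 = b1;
  }
  return logsum2(a0, a1);
}

// [[Rcpp::export]]
NumericMatrix hmm_posterior(NumericMatrix logdens, NumericMatrix logGamma,
                            NumericVector logdelta) {
  int n = logdens.nrow();
  NumericMatrix la(n, 2), lb(n, 2), post(n, 2);
  la(0, 0) = logdelta[0] + logdens(0, 0);
  la(0, 1) = logdelta[1] + logdens(0, 1);
  for (int t = 1; t < n; ++t) {
    la(t, 0) = logsum2(la(t - 1, 0) + logGamma(0, 0),
                       la(t - 1, 1) + logGamma(1, 0)) + logdens(t, 0);
    la(t, 1) = logsum2(la(t - 1, 0) + logGamma(0, 1),
                       la(t - 1, 1) + logGamma(1, 1)) + logdens(t, 1);
  }
  lb(n - 1, 0) = 0.0; lb(n - 1, 1) = 0.0;
  for (int t = n - 2; t >= 0; --t) {
    lb(t, 0) = logsum2(logGamma(0, 0) + logdens(t + 1, 0) + lb(t + 1, 0),
                       logGamma(0, 1) + logdens(t + 1, 1) + lb(t + 1, 1));
    lb(t, 1) = logsum2(logGamma(1, 0) + logdens(t + 1, 0) + lb(t + 1, 0),
                       logGamma(1, 1) + logdens(t + 1, 1) + lb(t + 1, 1));
  }
  for (int t = 0; t < n; ++t) {
    double l0 = la(t, 0) + lb(t, 0);
    double l1 = la(t, 1) + lb(t, 1);
    double norm = logsum2(l0, l1);
    post(t, 0) = std::exp(l0 - norm);
    post(t, 1) = std::exp(l1 - norm);
  }
  return post;
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericMatrix logGamma,
                          NumericVector logdelta) {
  int n = logdens.nrow();
  NumericMatrix v(n, 2);
  IntegerMatrix bp(n, 2);
  v(0, 0) = logdelta[0] + logdens(0, 0);
  v(0, 1) = logdelta[1] + logdens(0, 1);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      double c0 = v(t - 1, 0) + logGamma(0, s);
      double c1 = v(t - 1, 1) + logGamma(1, s);
      if (c0 >= c1) { v(t, s) = c0 + logdens(t, s); bp(t, s) = 0; }
      else { v(t, s) = c1 + logdens(t, s); bp(t, s) = 1; }
    }
  }
  IntegerVector path(n);
  path[n - 1] = v(n - 1, 0) >= v(n - 1, 1) ? 0 : 1;
  for (int t = n - 2; t >= 0; --t) path[t] = bp(t + 1, path[t + 1]);
  return path + 1;
}
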