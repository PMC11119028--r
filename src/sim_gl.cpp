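#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time update of the stochastic-neuron network with offset-logistic
// spiking-rate function. `u` is a (T x N) matrix of pre-drawn uniforms; the
// first K rows of the output are forced silent (the initial condition) and
// the recursion runs from row K+1. Weights: w(j, i) = weight of j onto i.
// [[Rcpp::export]]
IntegerMatrix sim_gl_logistic(NumericMatrix u, NumericMatrix w,
                              NumericVector beta, double offset, int K) {
  const int T = u.nrow(), N = u.ncol();
  IntegerMatrix x(T, N);
  for (int t = K; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double v;
      if (x(t - 1, i) == 1) {
        v = 0.0;  // reset after a spike
      } else {
        // last own spike in window t-K..t-1, truncated at t-K
        int L = t - K;
        for (int s = t - 1; s >= t - K; --s) {
          if (x(s, i) == 1) { L = s; break; }
        }
        double syn = 0.0;
        for (int j = 0; j < N; ++j) {
          double wji = w(j, i);
          if (wji == 0.0) continue;
          int cnt = 0;
          for (int s = L + 1; s <= t - 1; ++s) cnt += x(s, j);
          syn += wji * cnt;
        }
        v = beta[i] + syn / std::pow(2.0, t - L - 1);
      }
      double p = 1.0 / (1.0 + std::exp(-(v + offset)));
      x(t, i) = (u(t, i) < p) ? 1 : 0;
    }
  }
  return x;
}
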