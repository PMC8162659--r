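#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one observation sequence (Rabiner-style
// per-step normalisation; numerically equivalent to log-space recursions).
//
// B:  T x K state-conditional observation likelihoods
// A:  K x K row-stochastic transition matrix
// pi: K initial state distribution
//
// Returns the sequence log-likelihood, per-step posteriors gamma (T x K)
// and expected transition counts summed over steps (xi_sum, K x K).
// [[Rcpp::export]]
List fb_core(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  const int T = B.nrow(), K = B.ncol();
  if (T == 0 || K == 0) stop("empty observation sequence");
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi_sum(K, K);
  NumericVector c(T);
  double ll = 0.0;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (!(s > 0.0) || !std::isfinite(s))
    stop("non-finite forward probability at step 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  ll = std::log(s);
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (!(s > 0.0) || !std::isfinite(s))
      stop("non-finite forward probability at step " + std::to_string(t + 1));
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    ll += std::log(s);
  }

  // backward (scaled with the forward constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  // posteriors and expected transition counts
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g > 0.0) for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      const double aj = alpha(t, j);
      for (int k = 0; k < K; ++k) {
        xi_sum(j, k) += aj * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}
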