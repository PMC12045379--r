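#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state Gaussian-emission HMM.
// Returns log-likelihood, per-frame posteriors (gamma) and summed
// transition posteriors (xi), the sufficient statistics for EM.
// [[Rcpp::export]]
List hmm2_estep(NumericVector x, NumericVector mu, NumericVector sigma,
                NumericMatrix trans, NumericVector init) {
  const int n = x.size();
  NumericMatrix b(n, 2), alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector scale(n);
  const double tiny = 1e-300;

  for (int t = 0; t < n; ++t)
    for (int j = 0; j < 2; ++j)
      b(t, j) = R::dnorm(x[t], mu[j], sigma[j], 0) + tiny;

  // forward
  double s0 = 0.0;
  for (int j = 0; j < 2; ++j) { alpha(0, j) = init[j] * b(0, j); s0 += alpha(0, j); }
  scale[0] = s0 + tiny;
  for (int j = 0; j < 2; ++j) alpha(0, j) /= scale[0];
  for (int t = 1; t < n; ++t) {
    double st = 0.0;
    for (int j = 0; j < 2; ++j) {
      double a = alpha(t - 1, 0) * trans(0, j) + alpha(t - 1, 1) * trans(1, j);
      alpha(t, j) = a * b(t, j);
      st += alpha(t, j);
    }
    scale[t] = st + tiny;
    for (int j = 0; j < 2; ++j) alpha(t, j) /= scale[t];
  }

  // backward
  beta(n - 1, 0) = 1.0; beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t)
    for (int i = 0; i < 2; ++i) {
      double s = 0.0;
      for (int j = 0; j < 2; ++j) s += trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / scale[t + 1];
    }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);

  for (int t = 0; t < n; ++t) {
    double g = alpha(t, 0) * beta(t, 0) + alpha(t, 1) * beta(t, 1) + tiny;
    for (int j = 0; j < 2; ++j) gamma(t, j) = alpha(t, j) * beta(t, j) / g;
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double denom = 0.0;
    double tmp[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        tmp[i][j] = alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j);
        denom += tmp[i][j];
      }
    denom += tiny;
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi(i, j) += tmp[i][j] / denom;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding; returns 0-based state path.
// [[Rcpp::export]]
IntegerVector hmm2_viterbi(NumericVector x, NumericVector mu, NumericVector sigma,
                           NumericMatrix trans, NumericVector init) {
  const int n = x.size();
  NumericMatrix delta(n, 2);
  IntegerMatrix psi(n, 2);
  const double neginf = -std::numeric_limits<double>::infinity();
  double lt[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      lt[i][j] = trans(i, j) > 0 ? std::log(trans(i, j)) : neginf;

  for (int j = 0; j < 2; ++j)
    delta(0, j) = (init[j] > 0 ? std::log(init[j]) : neginf) +
                  R::dnorm(x[0], mu[j], sigma[j], 1);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < 2; ++j) {
      double c0 = delta(t - 1, 0) + lt[0][j];
      double c1 = delta(t - 1, 1) + lt[1][j];
      // ties resolved toward state 0 for determinism
      if (c0 >= c1) { delta(t, j) = c0; psi(t, j) = 0; }
      else          { delta(t, j) = c1; psi(t, j) = 1; }
      delta(t, j) += R::dnorm(x[t], mu[j], sigma[j], 1);
    }

  IntegerVector path(n);
  path[n - 1] = delta(n - 1, 0) >= delta(n - 1, 1) ? 0 : 1;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
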