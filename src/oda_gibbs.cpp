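#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Draw from N(mean, 1) restricted to the positive half-line when `positive`,
// to the negative half-line otherwise. Inverse-CDF in the upper tail so that
// extreme truncation regions (|mean| large) stay numerically stable.
static inline double rtrunc_std(double mean, bool positive) {
  double m = positive ? mean : -mean; // reduce to the z > 0 case
  double u = unif_rand();
  double z;
  double q = R::pnorm(m, 0.0, 1.0, 1, 0); // P(Z > -m)
  if (q > 1e-12) {
    z = m + R::qnorm((1.0 - u) * q, 0.0, 1.0, 0, 0);
  } else {
    // log-space path for deep truncation
    double lp = std::log1p(-u) + R::pnorm(m, 0.0, 1.0, 1, 1);
    z = m + R::qnorm(lp, 0.0, 1.0, 0, 1);
  }
  if (!(z > 0.0)) z = std::numeric_limits<double>::min();
  return positive ? z : -z;
}

// Orthogonal-data-augmentation Gibbs sampler for spike-and-slab variable
// selection. The complete design [X_o; X_a] has diagonal Gram matrix diag(d),
// so (gamma_j, beta_j) are conditionally independent across j given the
// complete response, and the conditional inclusion probabilities used for the
// Bernoulli draws double as the Rao-Blackwell estimator of the inclusion
// probabilities. Columns of X_o are centred, the augmented rows carry no
// intercept, hence the intercept (vague N(0, v0) prior) decouples as well.
// probit = true: y is 0/1 and latent utilities are drawn truncated-normal;
// probit = false: y is the (pre-scaled, unit residual variance) response.
// [[Rcpp::export]]
List oda_gibbs_cpp(const NumericMatrix& Xo, const NumericVector& y,
                   const NumericMatrix& Xa, const NumericVector& d,
                   double prior_pi, double tau2, double v0,
                   int n_iter, int n_burn, bool probit) {
  const int n = Xo.nrow(), p = Xo.ncol(), na = Xa.nrow();
  const int n_keep = n_iter - n_burn;
  if (n_keep <= 0) stop("n_iter must exceed n_burn");

  std::vector<double> beta(p, 0.0), zo(n), za(na), eta(n), rho(p);
  std::vector<double> rho_sum(p, 0.0), beta_sum(p, 0.0);
  std::vector<int> gamma(p, 0);
  double alpha = 0.0;
  IntegerMatrix gamma_draws(n_keep, p);

  if (!probit) for (int i = 0; i < n; ++i) zo[i] = y[i];

  const double log_pi = std::log(prior_pi);
  const double log_1mpi = std::log1p(-prior_pi);
  const double* X = Xo.begin();
  const double* A = Xa.begin();

  for (int it = 0; it < n_iter; ++it) {
    // (1) latent probit utilities for the observed block
    if (probit) {
      for (int i = 0; i < n; ++i) eta[i] = alpha;
      for (int j = 0; j < p; ++j) {
        const double bj = beta[j];
        if (bj != 0.0) {
          const double* col = X + (std::size_t)j * n;
          for (int i = 0; i < n; ++i) eta[i] += col[i] * bj;
        }
      }
      for (int i = 0; i < n; ++i) zo[i] = rtrunc_std(eta[i], y[i] > 0.5);
    }
    // (2) augmented responses
    for (int k = 0; k < na; ++k) {
      double mu = 0.0;
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) mu += A[(std::size_t)j * na + k] * beta[j];
      za[k] = mu + norm_rand();
    }
    // (3)+(4) per-coordinate complete-data estimate, inclusion draw, slab draw
    for (int j = 0; j < p; ++j) {
      const double* col = X + (std::size_t)j * n;
      const double* acol = A + (std::size_t)j * na;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += col[i] * zo[i];
      for (int k = 0; k < na; ++k) s += acol[k] * za[k];
      const double bh = s / d[j];
      const double v1 = 1.0 / d[j] + tau2;
      const double v0j = 1.0 / d[j];
      // log N(bh; 0, v) up to the shared -log(2*pi)/2
      const double lm1 = -0.5 * std::log(v1) - 0.5 * bh * bh / v1;
      const double lm0 = -0.5 * std::log(v0j) - 0.5 * bh * bh / v0j;
      const double r = 1.0 / (1.0 + std::exp(log_1mpi + lm0 - log_pi - lm1));
      rho[j] = r;
      const int g = (unif_rand() < r) ? 1 : 0;
      gamma[j] = g;
      if (g) {
        const double prec = d[j] + 1.0 / tau2;
        beta[j] = s / prec + norm_rand() / std::sqrt(prec);
      } else {
        beta[j] = 0.0;
      }
    }
    // (5) intercept: only observed rows carry it, and columns are centred
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += zo[i];
      const double prec = n + 1.0 / v0;
      alpha = s / prec + norm_rand() / std::sqrt(prec);
    }
    if (it >= n_burn) {
      const int r_it = it - n_burn;
      for (int j = 0; j < p; ++j) {
        rho_sum[j] += rho[j];
        beta_sum[j] += beta[j];
        gamma_draws(r_it, j) = gamma[j];
      }
    }
    if (((it + 1) & 255) == 0) {
      bool ok = R_FINITE(alpha);
      for (int j = 0; j < p && ok; ++j) ok = R_FINITE(beta[j]);
      if (!ok) stop("sampler state became non-finite at iteration %d", it + 1);
    }
  }

  NumericVector rho_out(p), beta_out(p);
  for (int j = 0; j < p; ++j) {
    rho_out[j] = rho_sum[j] / n_keep;
    beta_out[j] = beta_sum[j] / n_keep;
  }
  return List::create(_["rho"] = rho_out, _["gamma"] = gamma_draws,
                      _["beta_mean"] = beta_out);
}
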