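// Element-wise Gibbs sampler for sparse Bayesian non-negative matrix
// factorization: C ~ Normal(A %*% P, Sigma) element-wise, with a
// spike-and-slab sparsity prior on every element of A and P (point mass at
// zero with probability pi, else a unit-shape gamma slab with fixed scale).
// The exponential slab is conjugate up to truncation, so every conditional
// is an exact draw: a Bernoulli spike/slab choice with closed-form odds,
// then a truncated normal. Uses R's RNG stream, so results are reproducible
// from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// N(mu, sd^2) truncated to [0, Inf). Inverse-CDF in the body of the
// distribution, Robert (1995) exponential rejection in the far tail.
static double rtruncnorm_pos(double mu, double sd) {
  double alpha = -mu / sd;
  if (alpha < 4.0) {
    double p0 = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double u = R::unif_rand();
    double p = p0 + u * (1.0 - p0);
    if (p >= 1.0) p = 1.0 - 1e-16;
    double z = R::qnorm(p, 0.0, 1.0, 1, 0);
    double x = mu + sd * z;
    return x > 0.0 ? x : 0.0;
  }
  double lambda = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double z = alpha + R::exp_rand() / lambda;
    double d = z - lambda;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return mu + sd * z;
  }
}

// One spike-and-slab draw given the Gaussian pseudo-likelihood
// x ~ N(mu, 1/prec) (precision-weighted least squares summary) and prior
// pi * delta0 + (1 - pi) * Exp(rate beta).
static double draw_element(double prec, double m, double pi, double beta) {
  if (prec <= 0.0) {            // flat likelihood: draw from the prior
    if (pi > 0.0 && R::unif_rand() < pi) return 0.0;
    return R::exp_rand() / beta;
  }
  double s2 = 1.0 / prec;
  double sd = std::sqrt(s2);
  double mu = m * s2;
  double mut = mu - s2 * beta;   // slab conditional mean shift
  if (pi <= 0.0) return rtruncnorm_pos(mut, sd);
  if (pi >= 1.0) return 0.0;
  double log_odds = std::log1p(-pi) - std::log(pi) + std::log(beta)
    + 0.5 * std::log(2.0 * M_PI * s2)
    + R::pnorm(mut / sd, 0.0, 1.0, 1, 1)
    + 0.5 * mut * mut / s2;
  double p_slab = (log_odds > 35.0) ? 1.0
    : (log_odds < -35.0) ? 0.0
    : 1.0 / (1.0 + std::exp(-log_odds));
  if (R::unif_rand() < p_slab) return rtruncnorm_pos(mut, sd);
  return 0.0;
}

static double chi2_stat(const arma::mat& R, const arma::mat& W) {
  return arma::accu(arma::square(R) % W);
}

// [[Rcpp::export(name = ".gibbs_nmf")]]
List gibbs_nmf(const arma::mat& C, const arma::mat& S2,
               arma::mat A, arma::mat P,
               int n_burn, int n_sample, double zero_prob,
               double sparsity_scale, int trace_every) {
  const arma::uword F = C.n_rows, N = C.n_cols, K = A.n_cols;
  const double beta = 1.0 / sparsity_scale;
  arma::mat W = 1.0 / S2;           // precision weights
  arma::mat R = C - A * P;          // running residual
  const double init_chi2 = chi2_stat(R, W);

  arma::mat A_sum(F, K, arma::fill::zeros), P_sum(K, N, arma::fill::zeros);
  std::vector<double> trace;
  const int total = n_burn + n_sample;
  // spike disabled during the first half of burn-in: the dense posterior is
  // unimodal enough to find the right basin before sparsification kicks in
  const int n_anneal = n_burn / 2;

  for (int it = 0; it < total; ++it) {
    const double zero_prob_it = (it < n_anneal) ? 0.0 : zero_prob;
    // update A row by row
    for (arma::uword i = 0; i < F; ++i) {
      for (arma::uword k = 0; k < K; ++k) {
        double a_old = A(i, k);
        double prec = 0.0, m = 0.0;
        for (arma::uword j = 0; j < N; ++j) {
          double pkj = P(k, j);
          if (pkj == 0.0) continue;
          double w = W(i, j);
          prec += pkj * pkj * w;
          m += (R(i, j) + a_old * pkj) * pkj * w;
        }
        double a_new = draw_element(prec, m, zero_prob_it, beta);
        if (a_new != a_old) {
          double d = a_old - a_new;
          for (arma::uword j = 0; j < N; ++j) {
            double pkj = P(k, j);
            if (pkj != 0.0) R(i, j) += d * pkj;
          }
          A(i, k) = a_new;
        }
      }
    }
    // update P column by column
    for (arma::uword j = 0; j < N; ++j) {
      for (arma::uword k = 0; k < K; ++k) {
        double p_old = P(k, j);
        double prec = 0.0, m = 0.0;
        for (arma::uword i = 0; i < F; ++i) {
          double aik = A(i, k);
          if (aik == 0.0) continue;
          double w = W(i, j);
          prec += aik * aik * w;
          m += (R(i, j) + aik * p_old) * aik * w;
        }
        double p_new = draw_element(prec, m, zero_prob_it, beta);
        if (p_new != p_old) {
          double d = p_old - p_new;
          for (arma::uword i = 0; i < F; ++i) {
            double aik = A(i, k);
            if (aik != 0.0) R(i, j) += d * aik;
          }
          P(k, j) = p_new;
        }
      }
    }
    if (it >= n_burn) {
      A_sum += A;
      P_sum += P;
    }
    if (trace_every > 0 && ((it + 1) % trace_every == 0 || it + 1 == total))
      trace.push_back(chi2_stat(R, W));
    if ((it & 63) == 0) Rcpp::checkUserInterrupt();
  }

  arma::mat A_mean = A_sum / std::max(n_sample, 1);
  arma::mat P_mean = P_sum / std::max(n_sample, 1);
  arma::mat R_mean = C - A_mean * P_mean;
  double final_chi2 = chi2_stat(R_mean, W);

  return List::create(_["A"] = A_mean, _["P"] = P_mean,
                      _["chi2_trace"] = trace,
                      _["init_chi2"] = init_chi2,
                      _["final_chi2"] = final_chi2);
}
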