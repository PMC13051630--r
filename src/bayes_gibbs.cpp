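// Gibbs samplers for Bayesian whole-genome regression:
//   model 0 = BRR      (common marker-effect variance)
//   model 1 = Bayes A  (per-marker variances)
//   model 2 = Bayes B  (spike-and-slab, per-marker slab variances)
//   model 3 = Bayes C  (spike-and-slab, common slab variance)
// Uses R's RNG, so set.seed() on the R side makes chains reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rinvchisq(double nu, double scale) {
  // scaled-inverse-chi^2(nu, scale): nu * scale / chi2_nu
  return nu * scale / R::rchisq(nu);
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(const arma::vec& y, const arma::mat& X, int model,
               int n_iter, int burn_in, double nu, double Sb, double Se,
               double pi_init, bool sample_pi, double pi_a, double pi_b) {
  RNGScope scope;
  const int n = X.n_rows, p = X.n_cols;
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  double mu = arma::mean(y);
  arma::vec b(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::ones);
  double s2b = Sb, s2e = Se, pi = pi_init;
  arma::vec s2bj(p);
  s2bj.fill(Sb);
  const bool spike = (model == 2 || model == 3);

  arma::vec e = y - mu;                 // residual (b starts at zero)

  arma::vec b_sum(p, arma::fill::zeros);
  double mu_sum = 0, s2e_sum = 0, s2b_sum = 0, pi_sum = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double mu_new = R::rnorm(arma::mean(e) + mu, std::sqrt(s2e / n));
    e += (mu - mu_new);
    mu = mu_new;

    int m_in = 0;
    double ssb_in = 0;
    for (int j = 0; j < p; ++j) {
      const double bj_old = b(j);
      const double rhs = arma::dot(X.col(j), e) + xtx(j) * bj_old;
      const double slab = (model == 0 || model == 3) ? s2b : s2bj(j);
      double bj_new = 0;
      int dj = 1;
      if (spike) {
        const double v1 = xtx(j) * slab + s2e;
        double logodds = std::log(pi) - std::log(1.0 - pi) +
          0.5 * (std::log(s2e / v1) + rhs * rhs * slab / (s2e * v1));
        const double p_in = 1.0 / (1.0 + std::exp(-logodds));
        dj = (R::unif_rand() < p_in) ? 1 : 0;
      }
      if (dj == 1) {
        const double prec = xtx(j) + s2e / slab;
        bj_new = R::rnorm(rhs / prec, std::sqrt(s2e / prec));
      }
      if (bj_new != bj_old) e += X.col(j) * (bj_old - bj_new);
      b(j) = bj_new;
      delta(j) = dj;
      if (dj == 1) { ++m_in; ssb_in += bj_new * bj_new; }
      // per-marker variance (Bayes A / B)
      if (model == 1) {
        s2bj(j) = rinvchisq(nu + 1.0,
                            (nu * Sb + bj_new * bj_new) / (nu + 1.0));
      } else if (model == 2) {
        s2bj(j) = rinvchisq(nu + dj,
                            (nu * Sb + bj_new * bj_new) / (nu + dj));
      }
    }
    // common marker variance (BRR / Bayes C)
    if (model == 0) {
      s2b = rinvchisq(nu + p, (nu * Sb + arma::dot(b, b)) / (nu + p));
    } else if (model == 3) {
      s2b = rinvchisq(nu + m_in, (nu * Sb + ssb_in) / (nu + m_in));
    }
    // residual variance
    s2e = rinvchisq(nu + n, (nu * Se + arma::dot(e, e)) / (nu + n));
    // inclusion probability
    if (spike && sample_pi)
      pi = R::rbeta(pi_a + m_in, pi_b + p - m_in);
    if (spike) {
      if (pi >= 1.0) pi = 1.0 - 1e-12;
      if (pi <= 0.0) pi = 1e-12;
    }
    if (!std::isfinite(s2e) || !std::isfinite(mu) || !b.is_finite())
      stop("divergent chain at iteration %d (non-finite state)", it + 1);

    if (it >= burn_in) {
      b_sum += b;
      mu_sum += mu;
      s2e_sum += s2e;
      s2b_sum += (model == 1 || model == 2) ? arma::mean(s2bj) : s2b;
      pi_sum += pi;
      ++kept;
    }
  }
  return List::create(
    _["b"] = b_sum / kept,
    _["mu"] = mu_sum / kept,
    _["sigma2_e"] = s2e_sum / kept,
    _["sigma2_b"] = s2b_sum / kept,
    _["pi"] = pi_sum / kept,
    _["n_kept"] = kept);
}
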