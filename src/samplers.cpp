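// Single-site Gibbs sampler shared by BayesC and BayesGC.
//
// Model: y = 1*mu + sum_i I_i x_i s_i [+ u] + e,  e ~ N(0, D sigma_e2),
// where x_i is the centred genotype vector of SNP i, I_i ~ Bern(pi),
// s_i | I_i = 1 ~ N(0, sigma_m2), u ~ N(0, G sigma_pol2), and D = diag(1/w)
// with w the effective number of records (w = 0 masks an animal out of the
// likelihood entirely: validation animals).
//
// The indicator is sampled from its full conditional with s_i integrated
// out.  Writing lambda = sigma_e2 / sigma_m2, v_i = x_i' W x_i and
// rhs_i = x_i' W r (r the residual excluding SNP i's own contribution,
// W = diag(w)):
//
//   log odds(I_i = 1) = log(pi/(1-pi))
//                       + 0.5 * log(lambda / (lambda + v_i))
//                       + 0.5 * rhs_i^2 / (sigma_e2 * (lambda + v_i))
//   s_i | I_i = 1  ~  N(rhs_i / (v_i + lambda), sigma_e2 / (v_i + lambda))
//
// The polygenic vector is drawn jointly each cycle from its multivariate
// normal full conditional; its precision P = Ginv/sigma_pol2 + W/sigma_e2
// is constant over cycles, so the caller passes its lower Cholesky factor L
// once and each draw costs two triangular solves.
//
// Residuals are maintained incrementally and recomputed from scratch every
// `recompute_every` cycles; the maximum drift observed is returned.
//
// All randomness comes from R's RNG, so set.seed() in R makes runs
// reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_core(const arma::mat& X, const arma::vec& y, const arma::vec& w,
                double sigma_e2, double sigma_m2, double pi,
                const arma::mat& L, int n_cycles, int n_burnin,
                int recompute_every) {
  const int n = X.n_rows, m = X.n_cols;
  const bool polygenic = L.n_rows > 0;
  const double lambda = (sigma_m2 > 0.0) ? sigma_e2 / sigma_m2 : R_PosInf;
  const double sw = arma::accu(w);
  const double log_prior_odds =
      (pi > 0.0 && pi < 1.0) ? std::log(pi) - std::log1p(-pi) : 0.0;

  // weighted genotype columns and their weighted sums of squares
  arma::mat WX = X.each_col() % w;
  arma::vec v(m);
  for (int j = 0; j < m; ++j) v(j) = arma::dot(WX.col(j), X.col(j));

  arma::mat Lt;
  if (polygenic) Lt = L.t();

  double mu = 0.0;
  arma::vec s(m, arma::fill::zeros);
  arma::ivec incl(m, arma::fill::zeros);
  arma::vec u(n, arma::fill::zeros);
  arma::vec r = y;  // residual: y - mu - X(I*s) - u

  arma::vec gsum(n, arma::fill::zeros), usum(n, arma::fill::zeros);
  arma::vec isum(m, arma::fill::zeros), issum(m, arma::fill::zeros);
  double musum = 0.0, max_drift = 0.0;
  int kept = 0;

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    // --- intercept ---
    if (sw > 0.0) {
      double mean = arma::dot(w, r) / sw + mu;
      double mu_new = mean + norm_rand() * std::sqrt(sigma_e2 / sw);
      r += (mu - mu_new);
      mu = mu_new;
    }

    // --- SNP indicators and effects, in index order ---
    if (sigma_m2 > 0.0 && pi > 0.0) {
      for (int j = 0; j < m; ++j) {
        double rhs = arma::dot(WX.col(j), r);
        if (incl(j)) rhs += v(j) * s(j);  // exclude SNP j's own contribution
        double p1;
        if (pi >= 1.0) {
          p1 = 1.0;
        } else {
          double logodds = log_prior_odds
              + 0.5 * std::log(lambda / (lambda + v(j)))
              + 0.5 * rhs * rhs / (sigma_e2 * (lambda + v(j)));
          p1 = 1.0 / (1.0 + std::exp(-logodds));
        }
        double s_old = incl(j) ? s(j) : 0.0;
        if (unif_rand() < p1) {
          double c = v(j) + lambda;
          double s_new = rhs / c + norm_rand() * std::sqrt(sigma_e2 / c);
          r -= X.col(j) * (s_new - s_old);
          s(j) = s_new;
          incl(j) = 1;
        } else {
          if (incl(j)) r += X.col(j) * s_old;
          s(j) = 0.0;
          incl(j) = 0;
        }
      }
    }

    // --- polygenic vector ---
    if (polygenic) {
      r += u;
      arma::vec b = (w % r) / sigma_e2;
      arma::vec mvec = arma::solve(arma::trimatl(L), b);
      mvec = arma::solve(arma::trimatu(Lt), mvec);
      arma::vec z(n);
      for (int i = 0; i < n; ++i) z(i) = norm_rand();
      u = mvec + arma::solve(arma::trimatu(Lt), z);
      r -= u;
    }

    // --- residual bookkeeping ---
    if (recompute_every > 0 && cyc % recompute_every == 0) {
      arma::vec r_true = y - mu - u;
      for (int j = 0; j < m; ++j)
        if (incl(j)) r_true -= X.col(j) * s(j);
      double drift = arma::abs(r - r_true).max();
      if (drift > max_drift) max_drift = drift;
      r = r_true;
    }

    // --- accumulate posterior summaries ---
    if (cyc > n_burnin) {
      gsum += (y - mu - r);  // = X (I*s) + u, the genetic value
      usum += u;
      for (int j = 0; j < m; ++j) {
        isum(j) += incl(j);
        issum(j) += s(j);
      }
      musum += mu;
      ++kept;
    }
  }

  return List::create(
      _["gebv"] = gsum / kept,
      _["polygenic_mean"] = usum / kept,
      _["snp_inclusion_prob"] = isum / kept,
      _["snp_effect_mean"] = issum / kept,
      _["mu_mean"] = musum / kept,
      _["max_residual_drift"] = max_drift,
      _["n_kept"] = kept);
}
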