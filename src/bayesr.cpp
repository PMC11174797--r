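#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// BayesR Gibbs sampler for y = mu + X b + e with each marker effect in a
// four-component normal mixture N(0, gamma_k * sigma_g2), gamma typically
// (0, 1e-4, 1e-3, 1e-2). X must be column-centered and y standardized by the
// caller; back-scaling happens in R. Variance components follow scaled
// inverse chi-square updates; mixture proportions get a Dirichlet update.
// Uses R's RNG throughout (reproducible under set.seed()).
// [[Rcpp::export]]
List bayesr_gibbs_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::vec& gamma, const arma::vec& dir_prior,
                      int n_iter, int burn_in, int thin) {
  const arma::uword n = X.n_rows, m = X.n_cols, K = gamma.n_elem;
  arma::vec xtx(m);
  for (arma::uword j = 0; j < m; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));
  const double vary = arma::var(y);

  double mu = arma::mean(y);
  arma::vec b(m, arma::fill::zeros);
  arma::uvec cls(m, arma::fill::zeros);
  arma::vec pi(K, arma::fill::value(1.0 / K));
  double sigma_e2 = 0.5 * vary, sigma_g2 = 0.5 * vary;
  arma::vec r = y - mu;

  // weakly informative scaled-inv-chi2 priors centred on half the
  // phenotypic variance each
  const double nu_e = 4.0, S_e = 0.5 * vary;
  const double nu_g = 4.0, S_g = 0.5 * vary;

  arma::vec b_mean(m, arma::fill::zeros);
  arma::mat prob(m, K, arma::fill::zeros);
  double mu_mean = 0.0, se_mean = 0.0, sg_mean = 0.0, gvar_mean = 0.0;
  arma::vec pi_mean(K, arma::fill::zeros);
  int kept = 0;

  arma::vec logl(K), counts(K);
  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double mu_new = arma::mean(r) + mu + R::norm_rand() * std::sqrt(sigma_e2 / n);
    r += (mu - mu_new);
    mu = mu_new;

    // marker effects and class indicators
    counts.zeros();
    double ssb = 0.0;   // sum of b^2/gamma over non-null classes
    arma::uword nnz = 0;
    for (arma::uword j = 0; j < m; ++j) {
      const double rhs = arma::dot(X.col(j), r) + xtx[j] * b[j];
      logl[0] = std::log(pi[0]);
      for (arma::uword k = 1; k < K; ++k) {
        const double vk = gamma[k] * sigma_g2;
        const double C = xtx[j] / sigma_e2 + 1.0 / vk;
        logl[k] = std::log(pi[k]) - 0.5 * std::log(vk * C) +
          0.5 * rhs * rhs / (sigma_e2 * sigma_e2 * C);
      }
      const double lmax = logl.max();
      double tot = 0.0;
      for (arma::uword k = 0; k < K; ++k) tot += std::exp(logl[k] - lmax);
      double u = unif_rand() * tot;
      arma::uword knew = 0;
      for (arma::uword k = 0; k < K; ++k) {
        u -= std::exp(logl[k] - lmax);
        if (u <= 0.0) { knew = k; break; }
      }
      double bnew = 0.0;
      if (knew > 0) {
        const double vk = gamma[knew] * sigma_g2;
        const double C = xtx[j] / sigma_e2 + 1.0 / vk;
        bnew = rhs / (sigma_e2 * C) + R::norm_rand() / std::sqrt(C);
        ssb += bnew * bnew / gamma[knew];
        ++nnz;
      }
      if (b[j] != 0.0 || bnew != 0.0) r += X.col(j) * (b[j] - bnew);
      b[j] = bnew;
      cls[j] = knew;
      counts[knew] += 1.0;
    }

    // variance components (scaled inverse chi-square)
    sigma_g2 = (ssb + nu_g * S_g) / R::rchisq(nu_g + (double) nnz);
    sigma_e2 = (arma::dot(r, r) + nu_e * S_e) / R::rchisq(nu_e + (double) n);

    // mixture proportions
    double psum = 0.0;
    for (arma::uword k = 0; k < K; ++k) {
      pi[k] = R::rgamma(counts[k] + dir_prior[k], 1.0);
      psum += pi[k];
    }
    pi /= psum;

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++kept;
      b_mean += b;
      mu_mean += mu;
      se_mean += sigma_e2;
      sg_mean += sigma_g2;
      pi_mean += pi;
      for (arma::uword j = 0; j < m; ++j) prob(j, cls[j]) += 1.0;
      gvar_mean += arma::var(X * b);
    }
  }

  b_mean /= kept;
  prob /= kept;
  return List::create(
    _["beta"] = b_mean,
    _["class_probs"] = prob,
    _["mu"] = mu_mean / kept,
    _["sigma_e2"] = se_mean / kept,
    _["sigma_g2"] = sg_mean / kept,
    _["genic_var"] = gvar_mean / kept,
    _["pi"] = pi_mean / kept,
    _["n_kept"] = kept);
}
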