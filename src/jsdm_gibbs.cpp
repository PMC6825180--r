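// Multivariate probit Gibbs sampler (Albert-Chib latent-variable
// augmentation with a parameter-expanded inverse-Wishart covariance
// update rescaled to a correlation matrix).
//
// Model: y_ij = 1[z_ij > 0], z_i ~ N(Gamma' x_i, R), R a correlation
// matrix. Gamma is (p+1) x J (intercept row first); prior
// vec(Gamma) ~ N(0, prior_var I); expanded covariance prior
// IW(I_J, prior_df). All randomness comes from R's RNG so chains are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Standard-normal draw truncated to (a, Inf). Direct rejection near the
// bulk; Robert (1995) exponential rejection in the upper tail.
static double rtnorm_lower(double a) {
  if (a < 0.45) {
    double x;
    do { x = norm_rand(); } while (x <= a);
    return x;
  }
  const double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + exp_rand() / lambda;
    double d = x - lambda;
    if (std::log(unif_rand()) <= -0.5 * d * d) return x;
  }
}

// Inverse-Wishart(S, nu) draw via Bartlett decomposition of the
// corresponding Wishart(inv(S), nu).
static arma::mat rinvwishart(const arma::mat& S, double nu) {
  const arma::uword J = S.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(S), "lower");
  arma::mat A(J, J, arma::fill::zeros);
  for (arma::uword i = 0; i < J; ++i) {
    A(i, i) = std::sqrt(Rf_rchisq(nu - static_cast<double>(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat W = L * A;
  return arma::inv_sympd(W * W.t());
}

// [[Rcpp::export(name = ".jsdm_gibbs_chain")]]
List jsdm_gibbs_chain(const arma::mat& X, const arma::imat& Y,
                      int n_iter, int burnin, int thin,
                      double prior_var, double prior_df,
                      bool fix_identity) {
  const arma::uword n = X.n_rows, q = X.n_cols, J = Y.n_cols;
  if (n_iter <= burnin) stop("iterations must exceed burn-in");
  if (thin < 1) stop("thinning factor must be >= 1");

  const arma::mat XtX = X.t() * X;
  const int n_keep = (n_iter - burnin) / thin;
  arma::mat gamma_draws(n_keep, q * J);
  arma::mat R_draws(n_keep, J * J);

  arma::mat Gamma(q, J, arma::fill::zeros);
  arma::mat R(J, J, arma::fill::eye);
  arma::mat Z(n, J);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < J; ++j)
      Z(i, j) = Y(i, j) == 1 ? 0.5 : -0.5;

  const bool update_R = !fix_identity && J > 1;
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    // (a) latent z: truncated-normal draws from the full conditionals
    arma::mat Omega = arma::inv_sympd(R);
    arma::mat Mu = X * Gamma;
    for (arma::uword j = 0; j < J; ++j) {
      const double cvar = 1.0 / Omega(j, j);
      const double csd = std::sqrt(cvar);
      // cmean_i = mu_ij - cvar * sum_{k != j} Omega(j,k) (z_ik - mu_ik)
      arma::vec adj(n, arma::fill::zeros);
      for (arma::uword k = 0; k < J; ++k)
        if (k != j) adj += Omega(j, k) * (Z.col(k) - Mu.col(k));
      arma::vec cmean = Mu.col(j) - cvar * adj;
      for (arma::uword i = 0; i < n; ++i) {
        if (Y(i, j) == 1)
          Z(i, j) = cmean(i) + csd * rtnorm_lower(-cmean(i) / csd);
        else
          Z(i, j) = cmean(i) - csd * rtnorm_lower(cmean(i) / csd);
      }
    }

    // (b) coefficients: conjugate MVN draw of vec(Gamma)
    arma::mat P = arma::kron(Omega, XtX);
    P.diag() += 1.0 / prior_var;
    arma::vec b = arma::vectorise(X.t() * Z * Omega);
    arma::mat U = arma::chol(P);  // P = U'U
    arma::vec mean = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), b));
    arma::vec v(q * J);
    for (arma::uword i = 0; i < q * J; ++i) v(i) = norm_rand();
    arma::vec g = mean + arma::solve(arma::trimatu(U), v);
    Gamma = arma::reshape(g, q, J);

    // (c) residual correlation: parameter-expanded IW draw, rescaled to
    // correlation form; latents and coefficients rescaled to match
    if (update_R) {
      arma::mat E = Z - X * Gamma;
      arma::mat S = arma::eye<arma::mat>(J, J) + E.t() * E;
      arma::mat Sigma = rinvwishart(S, prior_df + static_cast<double>(n));
      arma::vec d = 1.0 / arma::sqrt(Sigma.diag());
      R = arma::diagmat(d) * Sigma * arma::diagmat(d);
      R = 0.5 * (R + R.t());
      R.diag().ones();
      for (arma::uword j = 0; j < J; ++j) {
        Z.col(j) *= d(j);
        Gamma.col(j) *= d(j);
      }
    }

    if (!Gamma.is_finite() || !Z.is_finite())
      stop("non-finite draw at iteration %d", t);

    if (t > burnin && (t - burnin) % thin == 0) {
      gamma_draws.row(kept) = arma::vectorise(Gamma).t();
      R_draws.row(kept) = arma::vectorise(R).t();
      ++kept;
    }
  }

  return List::create(_["gamma"] = gamma_draws, _["R"] = R_draws,
                      _["n_keep"] = kept);
}
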