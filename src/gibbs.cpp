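// Gibbs sampler for the Gaussian-copula graphical model with extended rank
// likelihood. Latent cells are updated one at a time from their univariate
// conditional Gaussian truncated to the window defined by the current
// latents of strictly lower / strictly higher observed levels; missing
// cells are drawn untruncated (in-sampler posterior-predictive imputation).
// The precision matrix is redrawn from its conjugate Wishart full
// conditional. All randomness comes from R's RNG so runs are reproducible
// from set.seed() and invariant to monotone margin transforms (which leave
// the level codes, hence the sampling path, unchanged).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Inverse-CDF truncated normal draw; falls back to the window midpoint
// when the probability mass of the window underflows (keeps the RNG
// stream aligned by still consuming one uniform).
static double rtnorm1(double mu, double sd, double lb, double ub) {
  if (lb == -INF && ub == INF) return R::rnorm(mu, sd);
  double a = (lb - mu) / sd, b = (ub - mu) / sd;
  double pa = (lb == -INF) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = (ub == INF) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa < 1e-14) {
    (void)unif_rand();
    if (lb != -INF && ub != INF) return mu + sd * 0.5 * (a + b);
    return (lb != -INF) ? lb : ub;
  }
  double u = R::runif(pa, pb);
  double z = R::qnorm(u, 0.0, 1.0, 1, 0);
  if (z < a) z = a;
  if (ub != INF && z > b) z = b;
  return mu + sd * z;
}

// Wishart(df, S) via Bartlett decomposition, R RNG.
static arma::mat rwish(double df, const arma::mat& S) {
  const arma::uword p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat partials(const arma::mat& K) {
  const arma::uword p = K.n_rows;
  arma::vec d = arma::sqrt(K.diag());
  arma::mat P = -K / (d * d.t());
  P.diag().zeros();
  return arma::symmatu(P);
}

// level_codes: n x p integers, 1..n_levels[j] for observed cells (codes
// follow the ascending order of observed values), 0 for missing.
// z_init:     n x p starting latents consistent with the codes.
// Returns cubes of retained partial-correlation and precision draws.
// [[Rcpp::export]]
List gibbs_copula_cpp(const IntegerMatrix level_codes,
                      const IntegerVector n_levels,
                      const arma::mat z_init,
                      const int n_draws, const int burn_in, const int thin,
                      const double prior_df, const arma::mat prior_rate) {
  const int n = level_codes.nrow(), p = level_codes.ncol();
  arma::mat Z = z_init;

  // per (variable, level) cell index lists; level 0 = missing
  std::vector<std::vector<std::vector<int>>> cells(p);
  for (int j = 0; j < p; ++j) {
    cells[j].assign(n_levels[j] + 1, {});
    for (int i = 0; i < n; ++i) cells[j][level_codes(i, j)].push_back(i);
  }

  arma::mat K = arma::eye(p, p);
  arma::cube P_draws(p, p, n_draws), K_draws(p, p, n_draws);
  const int total = burn_in + n_draws * thin;
  int kept = 0;

  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < p; ++j) {
      const double kjj = K(j, j);
      const double csd = std::sqrt(1.0 / kjj);
      arma::vec v = Z * K.col(j);
      const int L = n_levels[j];
      // suffix minima over levels of the current latents
      std::vector<double> suffmin(L + 2, INF);
      for (int l = L; l >= 1; --l) {
        double m = INF;
        for (int i : cells[j][l]) if (Z(i, j) < m) m = Z(i, j);
        suffmin[l] = std::min(m, suffmin[l + 1]);
      }
      double runmax = -INF;
      for (int l = 1; l <= L; ++l) {
        const double ub = suffmin[l + 1];
        double newmax = -INF;
        for (int i : cells[j][l]) {
          const double mu = Z(i, j) - v(i) / kjj;
          const double z = rtnorm1(mu, csd, runmax, ub);
          Z(i, j) = z;
          if (z > newmax) newmax = z;
        }
        if (newmax > runmax) runmax = newmax;
      }
      for (int i : cells[j][0]) {  // missing: posterior predictive
        const double mu = Z(i, j) - v(i) / kjj;
        Z(i, j) = R::rnorm(mu, csd);
      }
    }
    arma::mat S = prior_rate + Z.t() * Z;
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, S))
      stop("sampler error: non positive-definite scale matrix at iteration %d",
           it + 1);
    K = rwish(prior_df + n, Sinv);
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_draws) {
      P_draws.slice(kept) = partials(K);
      K_draws.slice(kept) = K;
      ++kept;
    }
  }
  return List::create(_["partials"] = P_draws, _["precision"] = K_draws,
                      _["latent_final"] = Z);
}
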