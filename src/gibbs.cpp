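// Single-site Gibbs sampler for the Cholesky-transformed animal model
//   y = X b + W c_a + e,   c_a ~ N(0, I sigma2_a),   e ~ N(0, I sigma2_e)
// where W = Z L V and L is the lower Cholesky factor of the relationship
// matrix (V an optional rotation making W'W diagonal), so a = (L V) c_a
// recovers breeding values for every pedigree animal.
//
// Posterior means of b, c_a and the variance components are accumulated at
// every post-burn-in iteration (the mean of a follows by linearity of the
// back-transform); per-animal posterior variances (the PEVs) come from
// thinned back-transformed samples, which need far less precision than the
// means. Residual-update scheme: each coefficient update costs O(n).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".gibbs_ssgblup")]]
List gibbs_ssgblup(const arma::vec& y,
                   const arma::mat& X,
                   const arma::mat& W,
                   const arma::mat& L,
                   int n_iter, int burn_in, int thin,
                   double df_a, double S_a,
                   double df_e, double S_e,
                   double fixed_sigma2_a, double fixed_sigma2_e,
                   double init_sigma2_a, double init_sigma2_e) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int N = W.n_cols;
  const bool fix_a = fixed_sigma2_a > 0.0;
  const bool fix_e = fixed_sigma2_e > 0.0;

  arma::vec b(p, arma::fill::zeros);
  arma::vec ca(N, arma::fill::zeros);
  double sigma2_a = fix_a ? fixed_sigma2_a : init_sigma2_a;
  double sigma2_e = fix_e ? fixed_sigma2_e : init_sigma2_e;

  arma::vec xtx(p), wtw(N);
  for (int k = 0; k < p; ++k) xtx[k] = arma::dot(X.col(k), X.col(k));
  for (int j = 0; j < N; ++j) wtw[j] = arma::dot(W.col(j), W.col(j));

  arma::vec e = y - X * b - W * ca;

  arma::vec b_sum(p, arma::fill::zeros), b_ss(p, arma::fill::zeros);
  arma::vec ca_sum(N, arma::fill::zeros);
  arma::vec a_sum(N, arma::fill::zeros), a_ss(N, arma::fill::zeros);
  double sa_sum = 0, sa_ss = 0, se_sum = 0, se_ss = 0, h2_sum = 0, h2_ss = 0;
  long n_kept = 0;  // every post-burn-in iteration
  int n_saved = 0;  // thinned samples (PEV accumulation)

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior
    for (int k = 0; k < p; ++k) {
      e += X.col(k) * b[k];
      double rhs = arma::dot(X.col(k), e);
      double bnew = rhs / xtx[k] + R::rnorm(0.0, std::sqrt(sigma2_e / xtx[k]));
      e -= X.col(k) * bnew;
      b[k] = bnew;
    }
    // transformed animal effects
    double lambda = sigma2_e / sigma2_a;
    for (int j = 0; j < N; ++j) {
      double cj = ca[j];
      double denom = wtw[j] + lambda;
      double cnew;
      if (wtw[j] > 0.0) {
        double rhs = arma::dot(W.col(j), e) + wtw[j] * cj;
        cnew = rhs / denom + R::rnorm(0.0, std::sqrt(sigma2_e / denom));
        if (cnew != cj) e += W.col(j) * (cj - cnew);
      } else {
        cnew = R::rnorm(0.0, std::sqrt(sigma2_a));  // pure prior coordinate
      }
      ca[j] = cnew;
    }
    // variance components, scaled-inverse-chi-square conjugate updates
    if (!fix_a) {
      double ss = arma::dot(ca, ca) + df_a * S_a;
      sigma2_a = ss / R::rchisq(df_a + N);
    }
    if (!fix_e) {
      double ss = arma::dot(e, e) + df_e * S_e;
      sigma2_e = ss / R::rchisq(df_e + n);
    }
    if (!std::isfinite(sigma2_a) || !std::isfinite(sigma2_e) ||
        !b.is_finite() || !ca.is_finite())
      stop("divergent chain at iteration %d", it + 1);

    if (it >= burn_in) {
      b_sum += b; b_ss += arma::square(b);
      ca_sum += ca;
      sa_sum += sigma2_a; sa_ss += sigma2_a * sigma2_a;
      se_sum += sigma2_e; se_ss += sigma2_e * sigma2_e;
      double h2 = sigma2_a / (sigma2_a + sigma2_e);
      h2_sum += h2; h2_ss += h2 * h2;
      ++n_kept;
      if ((it - burn_in) % thin == 0) {
        arma::vec a = L * ca;
        a_sum += a; a_ss += arma::square(a);
        ++n_saved;
      }
    }
  }
  if (n_saved < 2) stop("fewer than 2 stored samples; check chain settings");

  arma::vec b_mean = b_sum / n_kept;
  arma::vec b_var = (b_ss / n_kept - arma::square(b_mean)) *
    (double(n_kept) / double(n_kept - 1));
  b_var.transform([](double v) { return v < 0 ? 0.0 : v; });
  arma::vec a_mean = L * (ca_sum / n_kept);
  arma::vec a_thin_mean = a_sum / n_saved;
  arma::vec a_var = (a_ss / n_saved - arma::square(a_thin_mean)) *
    (double(n_saved) / double(n_saved - 1));
  a_var.transform([](double v) { return v < 0 ? 0.0 : v; });

  auto scal = [n_kept](double s, double ss) {
    double m = s / n_kept;
    double v = (ss / n_kept - m * m) * n_kept / (n_kept - 1.0);
    return NumericVector::create(_["mean"] = m,
                                 _["sd"] = std::sqrt(v < 0 ? 0 : v));
  };
  return List::create(
    _["b"] = List::create(_["mean"] = b_mean, _["var"] = b_var),
    _["a"] = List::create(_["mean"] = a_mean, _["var"] = a_var),
    _["sigma2_a"] = scal(sa_sum, sa_ss),
    _["sigma2_e"] = scal(se_sum, se_ss),
    _["h2"] = scal(h2_sum, h2_ss),
    _["n_saved"] = n_saved);
}
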