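// Collapsed likelihood computations for the Gaussian random-intercept-and-slope
// model. Random effects are always integrated in closed form; for the sampler
// the fixed-effect vector is additionally integrated under its normal prior,
// leaving a low-dimensional marginal posterior over the variance components.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Per-subject marginal covariance V_i = Z_i G Z_i' + sigma^2 I, Z_i = [1, t].
static mat subject_cov(const vec& t, double tau0, double tau1, double rho,
                       double sigma) {
  const uword n = t.n_elem;
  mat V(n, n);
  const double g00 = tau0 * tau0;
  const double g01 = rho * tau0 * tau1;
  const double g11 = tau1 * tau1;
  for (uword a = 0; a < n; ++a) {
    for (uword b = 0; b <= a; ++b) {
      double v = g00 + g01 * (t[a] + t[b]) + g11 * t[a] * t[b];
      if (a == b) v += sigma * sigma;
      V(a, b) = v;
      V(b, a) = v;
    }
  }
  return V;
}

// Marginal log likelihood of y with beta integrated out under N(0, s^2 I),
// plus (optionally) the Gaussian conditional posterior of beta given the
// variance components: beta | theta, y ~ N(A^{-1} b, A^{-1}),
// A = X'V^{-1}X + I/s^2, b = X'V^{-1}y.
// starts/ends: 0-based inclusive row ranges per subject.
// [[Rcpp::export]]
Rcpp::List cpp_collapsed_loglik(const arma::vec& y, const arma::mat& X,
                                const arma::ivec& starts, const arma::ivec& ends,
                                const arma::vec& times, double tau0, double tau1,
                                double rho, double sigma, double prior_sd,
                                bool want_beta) {
  const uword p = X.n_cols;
  const uword nsub = starts.n_elem;
  const uword ntot = y.n_elem;

  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  double logdetV = 0.0, quad = 0.0;
  bool ok = true;

  for (uword i = 0; i < nsub && ok; ++i) {
    const uword r0 = (uword)starts[i], r1 = (uword)ends[i];
    const vec ti = times.subvec(r0, r1);
    const mat V = subject_cov(ti, tau0, tau1, rho, sigma);
    mat L;
    if (!chol(L, V, "lower")) { ok = false; break; }
    const mat Xi = X.rows(r0, r1);
    const vec yi = y.subvec(r0, r1);
    // whitened blocks: L^{-1} X_i, L^{-1} y_i
    const mat Wx = solve(trimatl(L), Xi);
    const vec wy = solve(trimatl(L), yi);
    A += Wx.t() * Wx;
    b += Wx.t() * wy;
    quad += dot(wy, wy);
    logdetV += 2.0 * accu(log(L.diag()));
  }
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                              Rcpp::Named("ok") = false);
  }

  A.diag() += 1.0 / (prior_sd * prior_sd);
  mat LA;
  if (!chol(LA, A, "lower")) {
    return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                              Rcpp::Named("ok") = false);
  }
  const vec u = solve(trimatl(LA), b);      // LA^{-1} b
  const double logdetA = 2.0 * accu(log(LA.diag()));
  const double loglik = -0.5 * ((double)ntot * LOG2PI + logdetV + quad) -
                        (double)p * std::log(prior_sd) - 0.5 * logdetA +
                        0.5 * dot(u, u);

  if (!want_beta) {
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                              Rcpp::Named("ok") = true);
  }
  const vec m = solve(trimatu(LA.t()), u);  // A^{-1} b
  return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("post_mean") = m,
                            Rcpp::Named("chol_prec_lower") = LA);
}

// Total validation log likelihood for each posterior draw, random effects of
// every held-out subject marginalized in closed form.
// draws: S x (p + 4) matrix, columns = beta(1..p), tau0, tau1, rho, sigma.
// [[Rcpp::export]]
arma::vec cpp_predictive_totals(const arma::mat& draws, const arma::vec& y,
                                const arma::mat& X, const arma::ivec& starts,
                                const arma::ivec& ends, const arma::vec& times) {
  const uword p = X.n_cols;
  const uword S = draws.n_rows;
  const uword nsub = starts.n_elem;
  vec out(S);

  for (uword s = 0; s < S; ++s) {
    const rowvec d = draws.row(s);
    const vec beta = d.subvec(0, p - 1).t();
    const double tau0 = d[p], tau1 = d[p + 1], rho = d[p + 2], sigma = d[p + 3];
    const vec resid = y - X * beta;
    double tot = 0.0;
    bool ok = true;
    for (uword i = 0; i < nsub; ++i) {
      const uword r0 = (uword)starts[i], r1 = (uword)ends[i];
      const vec ti = times.subvec(r0, r1);
      const mat V = subject_cov(ti, tau0, tau1, rho, sigma);
      mat L;
      if (!chol(L, V, "lower")) { ok = false; break; }
      const vec w = solve(trimatl(L), resid.subvec(r0, r1));
      tot += -0.5 * ((double)ti.n_elem * LOG2PI) - accu(log(L.diag())) -
             0.5 * dot(w, w);
    }
    out[s] = ok ? tot : R_NegInf;
  }
  return out;
}
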