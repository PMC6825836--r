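// Ridge-penalized multinomial logistic regression by Newton-Raphson.
// The hot path of the imputation engine: one fit per bin per imputation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log-likelihood (unpenalized) given linear predictors eta (n x K-1),
// baseline category has eta = 0
static double mn_loglik(const mat& eta, const uvec& y) {
  double ll = 0.0;
  for (uword i = 0; i < eta.n_rows; ++i) {
    double mx = 0.0;
    for (uword k = 0; k < eta.n_cols; ++k) mx = std::max(mx, eta(i, k));
    double denom = std::exp(-mx);
    for (uword k = 0; k < eta.n_cols; ++k) denom += std::exp(eta(i, k) - mx);
    double lse = mx + std::log(denom);
    ll += (y(i) == 0 ? 0.0 : eta(i, y(i) - 1)) - lse;
  }
  return ll;
}

// y: 0..K-1 with 0 the reference category.  The first column of X is the
// intercept and is not penalized.  Returns coefficients p x (K-1).
// [[Rcpp::export]]
Rcpp::List multinom_ridge_cpp(const arma::mat& X, const arma::uvec& y, int K,
                              double ridge, int maxit, double tol) {
  const uword n = X.n_rows, p = X.n_cols, Km1 = (uword)K - 1;
  mat B(p, Km1, fill::zeros);

  vec pen_mask(p, fill::ones);
  pen_mask(0) = 0.0; // intercept unpenalized

  auto penalty = [&](const mat& Bm) {
    double s = 0.0;
    for (uword k = 0; k < Km1; ++k)
      s += dot(pen_mask % Bm.col(k), Bm.col(k));
    return 0.5 * ridge * s;
  };

  mat eta = X * B;
  double obj = mn_loglik(eta, y) - penalty(B);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxit; ++iter) {
    // probabilities for non-reference categories
    mat P(n, Km1);
    for (uword i = 0; i < n; ++i) {
      double mx = 0.0;
      for (uword k = 0; k < Km1; ++k) mx = std::max(mx, eta(i, k));
      double denom = std::exp(-mx);
      for (uword k = 0; k < Km1; ++k) denom += std::exp(eta(i, k) - mx);
      for (uword k = 0; k < Km1; ++k) P(i, k) = std::exp(eta(i, k) - mx) / denom;
    }

    // gradient and Hessian of the penalized log-likelihood
    vec g(p * Km1);
    mat H(p * Km1, p * Km1, fill::zeros);
    for (uword k = 0; k < Km1; ++k) {
      vec ind(n, fill::zeros);
      for (uword i = 0; i < n; ++i) if (y(i) == k + 1) ind(i) = 1.0;
      vec gk = X.t() * (ind - P.col(k)) - ridge * (pen_mask % B.col(k));
      g.subvec(k * p, (k + 1) * p - 1) = gk;
      for (uword l = k; l < Km1; ++l) {
        vec w = (l == k) ? vec(P.col(k) % (1.0 - P.col(k)))
                         : vec(-P.col(k) % P.col(l));
        mat Hkl = X.t() * (X.each_col() % w);
        if (l == k) Hkl.diag() += ridge * pen_mask;
        H.submat(k * p, l * p, (k + 1) * p - 1, (l + 1) * p - 1) = Hkl;
        if (l != k)
          H.submat(l * p, k * p, (l + 1) * p - 1, (k + 1) * p - 1) = Hkl.t();
      }
    }

    if (norm(g, "inf") < tol) { converged = true; break; }

    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-8 + 1e-8 * norm(H.diag(), "inf");
      step = solve(H, g);
    }

    // Newton step with halving on objective decrease
    double t = 1.0;
    mat Bnew;
    double objnew = -datum::inf;
    for (int h = 0; h < 30; ++h) {
      Bnew = B + t * reshape(step, p, Km1);
      mat etanew = X * Bnew;
      objnew = mn_loglik(etanew, y) - penalty(Bnew);
      if (std::isfinite(objnew) && objnew >= obj - 1e-12) { eta = etanew; break; }
      t *= 0.5;
    }
    double improve = objnew - obj;
    B = Bnew;
    obj = objnew;
    if (std::abs(improve) < tol * (std::abs(obj) + 1.0)) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("coef") = B,
    Rcpp::Named("loglik") = mn_loglik(X * B, y),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter);
}

// category probabilities (n x K) under coefficients B (p x K-1)
// [[Rcpp::export]]
arma::mat multinom_prob_cpp(const arma::mat& X, const arma::mat& B) {
  mat eta = X * B;
  const uword n = X.n_rows, Km1 = B.n_cols;
  mat P(n, Km1 + 1);
  for (uword i = 0; i < n; ++i) {
    double mx = 0.0;
    for (uword k = 0; k < Km1; ++k) mx = std::max(mx, eta(i, k));
    double denom = std::exp(-mx);
    for (uword k = 0; k < Km1; ++k) denom += std::exp(eta(i, k) - mx);
    P(i, 0) = std::exp(-mx) / denom;
    for (uword k = 0; k < Km1; ++k) P(i, k + 1) = std::exp(eta(i, k) - mx) / denom;
  }
  return P;
}
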