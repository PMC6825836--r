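# Thin R wrappers around the RcppArmadillo Newton solver for
# ridge-penalized multinomial (polytomous) logistic regression.
# Category 1 is the reference; X must carry an intercept in column 1,
# which is never penalized.

fit_multinom_ridge <- function(X, y_codes, K, ridge = 1e-5,
                               maxit = 30L, tol = 1e-6) {
  stopifnot(is.matrix(X), length(y_codes) == nrow(X), K >= 2)
  fit <- multinom_ridge_cpp(X, as.integer(y_codes) - 1L, as.integer(K),
                            ridge, as.integer(maxit), tol)
  fit$n_par <- length(fit$coef)
  fit
}

predict_multinom <- function(fit, X) {
  multinom_prob_cpp(X, fit$coef)
}

# BIC of a (near-)unpenalized multinomial fit: -2 loglik + n_par log(n)
multinom_bic <- function(X, y_codes, K, ridge = 1e-8) {
  fit <- fit_multinom_ridge(X, y_codes, K, ridge = ridge)
  -2 * fit$loglik + fit$n_par * log(nrow(X))
}
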