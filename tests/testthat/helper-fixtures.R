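# small fixtures built in code, shared across test files

tiny_cohort <- function(n = 6) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    age = c(40, 60, 55, 70, 45, 58)[seq_len(n)],
    sex = factor(c("male", "female", "male", "male", "female",
                   "female")[seq_len(n)],
                 levels = c("female", "male")),
    smoking = factor(c("never", "former", "current", "never", "former",
                       "never")[seq_len(n)],
                     levels = c("never", "former", "current"))
  )
}

# cohort with controlled male/age-57 composition for missingness arithmetic
composed_cohort <- function(n, frac_male57) {
  n_m57 <- round(n * frac_male57)
  tibble::tibble(
    sample_id = sprintf("id%06d", seq_len(n)),
    age = c(rep(60, n_m57), rep(40, n - n_m57)),
    sex = factor(c(rep("male", n_m57), rep("female", n - n_m57)),
                 levels = c("female", "male")),
    smoking = factor(rep(c("never", "former", "current"), length.out = n),
                     levels = c("never", "former", "current"))
  )
}

# normal-equations OLS oracle, independent of the package's fitting path
ols_oracle <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  list(beta = drop(beta), se = sqrt(diag(XtXi) * sigma2), df = df)
}
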