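# Per-site association model: methylation ~ age + sex + smoking (OLS, never
# reference), fitted for all sites of a bin at once via a multi-response
# least-squares solve, plus Rubin's-rules pooling with Barnard-Rubin
# degrees of freedom.

# Design matrix for the analysis model.  Sex is a 0/1 male indicator
# (female reference), age in years uncentred, smoking dummies against
# "never".  A smoking level absent from the data drops its column; the
# corresponding coefficient is reported NA (inestimable).
build_ewas_design <- function(covariates) {
  n <- nrow(covariates)
  former <- as.numeric(covariates$smoking == "former")
  current <- as.numeric(covariates$smoking == "current")
  X <- cbind(`(Intercept)` = rep(1, n), age = as.numeric(covariates$age),
             sex = sex_indicator(covariates$sex),
             former = former, current = current)
  keep <- c(TRUE, TRUE, TRUE, sum(former) > 0, sum(current) > 0)
  list(X = X[, keep, drop = FALSE], has_former = keep[4L],
       has_current = keep[5L])
}

# OLS of every site (columns of Y) on X; returns former/current estimates,
# their SEs and the residual df
fit_ewas_matrix <- function(Y, design) {
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("fewer cases than model parameters", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient EWAS design", call. = FALSE)
  coefs <- qr.coef(qrX, Y)                      # p x n_sites
  resid <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))
  nm <- colnames(X)
  pick <- function(term) {
    if (term == "former" && !design$has_former) return(NULL)
    if (term == "current" && !design$has_current) return(NULL)
    j <- match(term, nm)
    list(beta = unname(coefs[j, ]), se = unname(sqrt(xtx_inv_diag[j] * sigma2)))
  }
  ns <- ncol(Y)
  na <- rep(NA_real_, ns)
  f <- pick("former")
  cc <- pick("current")
  list(beta_former = if (is.null(f)) na else f$beta,
       se_former = if (is.null(f)) na else f$se,
       beta_current = if (is.null(cc)) na else cc$beta,
       se_current = if (is.null(cc)) na else cc$se,
       df = df)
}

#' Fit the per-site EWAS model on one (complete) dataset
#'
#' Ordinary least squares of each site's standardized methylation on age,
#' sex and smoking status (reference "never"), with two-sided t p-values.
#' Used directly for the complete-data "truth" and complete-case analyses;
#' MI strategies fit it once per imputation and pool with [pool_rubin()].
#'
#' @param methylation Standardized sites x individuals matrix (or
#'   site_id-keyed data frame); columns must align with `covariates` rows.
#' @param covariates Fully observed covariate tibble with `age`, `sex`,
#'   `smoking`.  Rows with missing values are dropped (complete-case
#'   analysis) with the matching methylation columns.
#' @param alpha Family-wise error level for the Bonferroni rule.
#' @param n_tests Number of tests for the Bonferroni threshold (defaults to
#'   the number of sites).
#' @param smoking_test `"min-p"` flags a site when either smoking
#'   coefficient passes the Bonferroni threshold; `"joint-F"` uses the
#'   2-df F test of both coefficients (single-dataset fits only).
#' @return A `pooled_ewas` tibble (one row per site) with columns
#'   `site_id`, `beta_former`, `se_former`, `df_former`, `p_former`, the
#'   `current` equivalents, and `significant`; between-imputation variance
#'   is zero here, so `df` equals the residual df.
#' @export
#' @examples
#' cohort <- simulate_cohort(120, seed = 1)
#' sim <- simulate_methylation(cohort, 50, 5, seed = 1)
#' res <- run_ewas(sim$methylation, cohort)
#' dplyr::filter(res, significant)
run_ewas <- function(methylation, covariates, alpha = 0.05, n_tests = NULL,
                     smoking_test = c("min-p", "joint-F")) {
  smoking_test <- match.arg(smoking_test)
  methylation <- as_methylation_matrix(methylation)
  stopifnot(ncol(methylation) == nrow(covariates))
  keep <- stats::complete.cases(
    covariates[, intersect(c("age", "sex", "smoking"), names(covariates))])
  cov_cc <- covariates[keep, , drop = FALSE]
  Y <- t(methylation[, keep, drop = FALSE])
  design <- build_ewas_design(cov_cc)
  fit <- fit_ewas_matrix(Y, design)
  n_tests <- n_tests %||% nrow(methylation)
  tstat <- function(b, s) 2 * pt(-abs(b / s), fit$df)
  out <- tibble::tibble(
    site_id = rownames(methylation),
    beta_former = fit$beta_former, se_former = fit$se_former,
    df_former = as.numeric(fit$df), p_former = tstat(fit$beta_former,
                                                     fit$se_former),
    beta_current = fit$beta_current, se_current = fit$se_current,
    df_current = as.numeric(fit$df), p_current = tstat(fit$beta_current,
                                                       fit$se_current)
  )
  if (smoking_test == "joint-F" && design$has_former && design$has_current) {
    # 2-df Wald F for (former, current) jointly; needs the off-diagonal of
    # the coefficient covariance, so recompute from the design
    XtXi <- chol2inv(qr.R(qr(design$X)))
    jj <- match(c("former", "current"), colnames(design$X))
    V2 <- XtXi[jj, jj]
    V2i <- solve(V2)
    sigma2 <- (fit$se_former / sqrt(XtXi[jj[1], jj[1]]))^2
    B <- rbind(fit$beta_former, fit$beta_current)
    wald <- colSums(B * (V2i %*% B)) / (2 * sigma2)
    out$p_joint <- pf(wald, 2, fit$df, lower.tail = FALSE)
    out$significant <- out$p_joint < alpha / n_tests
  } else {
    out$significant <- pmin(out$p_former, out$p_current, na.rm = TRUE) <
      alpha / n_tests
  }
  new_pooled_ewas(out, strategy = "complete_data", m = 1L, alpha = alpha,
                  n_tests = n_tests)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Given `m` estimates and standard errors per quantity: the pooled
#' estimate is the mean `qbar`; within-imputation variance `W` is the mean
#' squared SE; between-imputation variance `B` is the sample variance of
#' the estimates (denominator `m - 1`); total variance
#' `T = W + (1 + 1/m) B`.  Degrees of freedom use the Barnard-Rubin
#' small-sample formula with complete-data df `df_com`; when `B = 0` the
#' pooled fit degenerates to the single fit with `df = df_com`.
#'
#' @param estimates Numeric matrix (`m` x quantities) or length-`m` vector.
#' @param std_errors Matching standard errors.
#' @param df_com Complete-data residual degrees of freedom.
#' @return Tibble with one row per quantity: `qbar`, `W`, `B`, `total`
#'   (Rubin's T), `se`, `df`, `p` (two-sided t).
#' @export
#' @examples
#' pool_rubin(c(0, 2), c(1, 1), df_com = 100)  # W 1, B 2, T 4, se 2
pool_rubin <- function(estimates, std_errors, df_com) {
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1L)
  if (is.vector(std_errors)) std_errors <- matrix(std_errors, ncol = 1L)
  stopifnot(all(dim(estimates) == dim(std_errors)), nrow(estimates) >= 2)
  m <- nrow(estimates)
  qbar <- colMeans(estimates)
  W <- colMeans(std_errors^2)
  B <- apply(estimates, 2L, var)
  total <- W + (1 + 1 / m) * B
  se <- sqrt(total)
  df <- barnard_rubin_df(m, B, total, df_com)
  p <- 2 * pt(-abs(qbar / se), df)
  tibble::tibble(qbar = qbar, W = W, B = B, total = total, se = se,
                 df = df, p = p)
}

# Barnard & Rubin (1999) adjusted df; vectorized over quantities
barnard_rubin_df <- function(m, B, total, df_com) {
  lambda <- (1 + 1 / m) * B / total
  lambda[total == 0] <- 0
  df_old <- (m - 1) / pmax(lambda^2, .Machine$double.eps)
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  df <- df_old * df_obs / (df_old + df_obs)
  df[B == 0] <- df_com
  df
}

# pool former/current coefficient matrices (m x sites) into result columns
pool_smoking_fits <- function(site_ids, bf, sf, bc, sc, df_com) {
  pf_ <- pool_columns(bf, sf, df_com)
  pc_ <- pool_columns(bc, sc, df_com)
  tibble::tibble(
    site_id = site_ids,
    beta_former = pf_$qbar, se_former = pf_$se, df_former = pf_$df,
    p_former = pf_$p,
    beta_current = pc_$qbar, se_current = pc_$se, df_current = pc_$df,
    p_current = pc_$p
  )
}

# fast matrix-form Rubin pooling (columns are sites); NA estimates (an
# inestimable coefficient in any imputation) give NA pooled values
pool_columns <- function(est, se2m, df_com) {
  m <- nrow(est)
  qbar <- colMeans(est)
  W <- colMeans(se2m^2)
  B <- colSums((est - rep(qbar, each = m))^2) / (m - 1)
  total <- W + (1 + 1 / m) * B
  se <- sqrt(total)
  df <- barnard_rubin_df(m, B, total, df_com)
  list(qbar = qbar, se = se, df = df, p = 2 * pt(-abs(qbar / se), df))
}

#' Bonferroni-significant sites of a results table
#'
#' A site is significant when the smaller of its two smoking p-values is
#' below `alpha / n_tests` — the "(current or former)" reading of
#' genome-wide significance.
#'
#' @param results A pooled EWAS tibble.
#' @param alpha Family-wise error level.
#' @param n_tests Number of tests (defaults to the table's `n_tests`
#'   attribute, else its row count).
#' @param rule `"min-p"` (default) or `"joint-F"` (requires a `p_joint`
#'   column, produced by [run_ewas()] with `smoking_test = "joint-F"`).
#' @return Character vector of significant site IDs, in ascending order of
#'   their minimum p-value.
#' @export
significant_sites <- function(results, alpha = 0.05, n_tests = NULL,
                              rule = c("min-p", "joint-F")) {
  rule <- match.arg(rule)
  n_tests <- n_tests %||% attr(results, "n_tests") %||% nrow(results)
  if (rule == "joint-F") {
    if (!"p_joint" %in% names(results))
      stop("no p_joint column; rerun run_ewas(smoking_test = 'joint-F')",
           call. = FALSE)
    p <- results$p_joint
  } else {
    p <- pmin(results$p_former, results$p_current, na.rm = TRUE)
  }
  hit <- which(p < alpha / n_tests)
  results$site_id[hit[order(p[hit])]]
}

new_pooled_ewas <- function(tbl, strategy, m, alpha, n_tests, n_bins = NA_integer_,
                            selected = character()) {
  structure(tbl, class = c("pooled_ewas", class(tibble::tibble())),
            strategy = strategy, m = m, alpha = alpha, n_tests = n_tests,
            n_bins = n_bins, selected = selected)
}
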