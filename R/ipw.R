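#' Inverse-probability weights for complete-case representativeness
#'
#' Fits a logistic regression of the completeness indicator on fully
#' observed predictors and weights each complete case by the inverse of its
#' fitted completeness probability, so the weighted complete cases
#' represent the full cohort.  Weights can be stabilized by the marginal
#' completeness rate and trimmed symmetrically at a quantile of the
#' complete-case weight distribution (winsorized to the bounds).
#'
#' @param covariates Covariate tibble.
#' @param predictors Fully observed columns of the missingness model
#'   (default age and sex).
#' @param complete Optional logical completeness indicator; by default a
#'   row is complete when it has no `NA` in any column.
#' @param stabilize Multiply weights by the marginal completeness rate
#'   (default `TRUE`), so they sum to about the number of complete cases.
#' @param trim_quantile Symmetric trimming quantile in `(0.5, 1]`; `1`
#'   disables trimming.  Default 0.99.
#' @return Tibble `sample_id`, `complete`, `prob` (fitted completeness
#'   probability), `weight` (0 for incomplete cases), `trimmed`.
#' @export
#' @examples
#' cohort <- simulate_cohort(500, seed = 1)
#' miss <- apply_missingness(cohort, mm1(), seed = 1)
#' w <- estimate_weights(miss)
#' summary(w$weight[w$complete])
estimate_weights <- function(covariates, predictors = c("age", "sex"),
                             complete = NULL, stabilize = TRUE,
                             trim_quantile = 0.99) {
  stopifnot(trim_quantile > 0.5, trim_quantile <= 1)
  if (is.null(complete)) complete <- stats::complete.cases(covariates)
  for (v in predictors) {
    if (anyNA(covariates[[v]]))
      stop("missingness-model predictor '", v, "' has missing values",
           call. = FALSE)
  }
  if (all(complete)) {
    return(tibble::tibble(sample_id = covariates$sample_id,
                          complete = complete, prob = 1,
                          weight = 1, trimmed = FALSE))
  }
  if (!any(complete)) stop("no complete cases", call. = FALSE)
  X <- build_predictor_matrix(covariates, predictors)
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(complete), family = binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0 # aliased (collinear) columns drop out
  eta <- drop(X %*% cf)
  prob <- 1 / (1 + exp(-eta))
  # the model separates completeness perfectly (fitted probabilities all
  # 0/1), or a complete case has fitted completeness ~ 0 so its weight
  # would explode
  separated <- all(prob[complete] > 1 - 1e-6) &&
    all(prob[!complete] < 1e-6)
  if (separated || min(prob[complete]) < 1e-6)
    stop("(near-)perfect separation in the missingness model; use fewer ",
         "predictors or trimming", call. = FALSE)
  weight <- ifelse(complete, 1 / prob, 0)
  if (stabilize) weight <- weight * mean(complete)
  trimmed <- rep(FALSE, length(weight))
  if (trim_quantile < 1) {
    wc <- weight[complete]
    bounds <- quantile(wc, c(1 - trim_quantile, trim_quantile))
    trimmed <- complete & (weight < bounds[1] | weight > bounds[2])
    weight[complete] <- pmin(pmax(weight[complete], bounds[1]), bounds[2])
  }
  tibble::tibble(sample_id = covariates$sample_id, complete = complete,
                 prob = prob, weight = weight, trimmed = trimmed)
}

#' Inverse-probability-weighted EWAS
#'
#' Weighted least squares of each site on age, sex and smoking over the
#' complete cases, with heteroskedasticity-robust (HC0 sandwich) standard
#' errors that account for the weighting.  Output has the same shape and
#' significance rule as the MI strategies, so the comparator drops into
#' the same evaluation pipeline.
#'
#' @param methylation Standardized sites x individuals matrix.
#' @param covariates Covariate tibble (missing smoking defines the
#'   incomplete cases).
#' @param weights Output of [estimate_weights()]; defaults to estimating
#'   them from age and sex.
#' @param alpha,n_tests Bonferroni significance rule.
#' @return A `pooled_ewas` tibble.
#' @export
run_ipw_ewas <- function(methylation, covariates, weights = NULL,
                         alpha = 0.05, n_tests = NULL) {
  methylation <- as_methylation_matrix(methylation)
  stopifnot(ncol(methylation) == nrow(covariates))
  if (is.null(weights)) weights <- estimate_weights(covariates)
  keep <- weights$complete & stats::complete.cases(
    covariates[, intersect(c("age", "sex", "smoking"), names(covariates))])
  w <- weights$weight[keep]
  cov_cc <- covariates[keep, , drop = FALSE]
  design <- build_ewas_design(cov_cc)
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("effective sample smaller than the model", call. = FALSE)
  Y <- t(methylation[, keep, drop = FALSE])

  A <- X * w
  bread <- solve(crossprod(X, A))             # (X'WX)^-1
  coefs <- bread %*% crossprod(A, Y)          # p x sites
  resid <- Y - X %*% coefs
  E2 <- (resid * w)^2                         # (w_i e_is)^2
  ns <- ncol(Y)
  # sandwich meat per site from the p(p+1)/2 cross-products of X columns
  se_mat <- matrix(NA_real_, p, ns)
  cross <- array(0, dim = c(p, p, ns))
  for (j in seq_len(p)) {
    for (k in j:p) {
      mjk <- colSums(X[, j] * X[, k] * E2)
      cross[j, k, ] <- mjk
      cross[k, j, ] <- mjk
    }
  }
  for (s in seq_len(ns)) {
    V <- bread %*% cross[, , s] %*% bread
    se_mat[, s] <- sqrt(diag(V))
  }
  rn <- colnames(X)
  df <- n - p
  get <- function(term) {
    j <- match(term, rn)
    if (is.na(j)) list(beta = rep(NA_real_, ns), se = rep(NA_real_, ns))
    else list(beta = unname(coefs[j, ]), se = unname(se_mat[j, ]))
  }
  f <- get("former"); cc <- get("current")
  n_tests <- n_tests %||% nrow(methylation)
  tp <- function(b, s) 2 * pt(-abs(b / s), df)
  out <- tibble::tibble(
    site_id = rownames(methylation),
    beta_former = f$beta, se_former = f$se, df_former = as.numeric(df),
    p_former = tp(f$beta, f$se),
    beta_current = cc$beta, se_current = cc$se,
    df_current = as.numeric(df), p_current = tp(cc$beta, cc$se))
  out$significant <- pmin(out$p_former, out$p_current, na.rm = TRUE) <
    alpha / n_tests
  new_pooled_ewas(out, strategy = "ipw", m = 1L, alpha = alpha,
                  n_tests = n_tests)
}
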