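#' Multiple imputation of a categorical covariate by polytomous regression
#'
#' For each of `m` imputations the engine (1) bootstrap-resamples the
#' complete cases, (2) fits a ridge-penalized multinomial logistic model of
#' the target on the predictors to the resample (the bootstrap step
#' propagates parameter uncertainty, making the imputation "proper"), and
#' (3) draws a category for every missing case from its fitted
#' probabilities.  Observed values are never altered.  If a bootstrap
#' resample loses an observed category it is redrawn (at most 10 attempts).
#'
#' @param data Covariate tibble.
#' @param target Name of the (factor) column with missing values.
#' @param predictors Names of fully observed covariate columns entering the
#'   imputation model (factors expand to reference-coded dummies).
#' @param extra Optional numeric matrix of additional predictors aligned to
#'   the rows of `data` — typically standardized methylation at the sites of
#'   one bin, individuals in rows.
#' @param m Number of imputations (`>= 2`).
#' @param ridge Ridge penalty on non-intercept coefficients; the small
#'   default keeps fits finite when many near-collinear sites enter the
#'   model.
#' @param seed Integer seed; imputation `i` draws from the sub-stream
#'   `stream_seed(seed, "imp", i)`.
#' @param boot If `TRUE` (default) each imputation refits on a bootstrap
#'   resample of the complete cases, propagating parameter uncertainty
#'   (proper MI); `FALSE` fits once and draws all imputations from the
#'   fitted probabilities, as mice's polyreg does.
#' @return An `imputations` object; see [complete_datasets()].
#' @export
#' @examples
#' cohort <- simulate_cohort(200, seed = 1)
#' miss <- apply_missingness(cohort, mm1(), seed = 1)
#' imp <- impute_polytomous(miss, "smoking", c("age", "sex"), m = 5, seed = 1)
#' head(complete_datasets(imp, 1))
impute_polytomous <- function(data, target, predictors = c("age", "sex"),
                              extra = NULL, m = 100, ridge = 1e-5,
                              seed = 1L, boot = TRUE) {
  stopifnot(m >= 2, target %in% names(data))
  y <- data[[target]]
  if (!is.factor(y)) y <- factor(y)
  miss <- is.na(y)
  X <- build_predictor_matrix(data, predictors, extra)
  obs <- which(!miss)
  draws <- matrix(NA_character_, nrow = sum(miss), ncol = m)
  if (any(miss)) {
    yobs <- droplevels(factor(y[obs]))
    codes <- as.integer(yobs)
    lev <- levels(yobs)
    K <- length(lev)
    Xobs <- X[obs, , drop = FALSE]
    Xmis <- X[miss, , drop = FALSE]
    pr <- NULL
    if (!boot && K > 1L) {
      if (ncol(Xobs) >= nrow(Xobs))
        stop("imputation model has as many predictors (", ncol(Xobs),
             ") as complete cases (", nrow(Xobs), "); use smaller bins",
             call. = FALSE)
      fit <- fit_multinom_ridge(Xobs, codes, K, ridge = ridge)
      pr <- predict_multinom(fit, Xmis)
    }
    for (i in seq_len(m)) {
      with_stream(stream_seed(seed, "imp", i), {
        draws[, i] <- if (boot || K == 1L)
          draw_categorical_core(Xobs, codes, K, lev, Xmis, ridge)
        else draw_from_probs(pr, lev)
      })
    }
  }
  new_imputations(data, m, seed, stats::setNames(
    list(list(method = "polytomous", miss = which(miss), draws = draws)),
    target))
}

#' Multiple imputation of a continuous covariate by predictive mean matching
#'
#' Each imputation perturbs a linear fit by the Bayesian bootstrap
#' (exponential weights on the complete cases), predicts the missing cases,
#' and gives each one the observed value of a donor drawn uniformly from the
#' `donors` complete cases whose (unperturbed) predicted means lie nearest
#' the case's perturbed prediction; ties are broken at random.  Imputed
#' values are therefore always members of the observed value set.
#'
#' @inheritParams impute_polytomous
#' @param donors Size of the donor pool (default 5).
#' @export
impute_pmm <- function(data, target, predictors = c("age", "sex"),
                       extra = NULL, m = 100, donors = 5, seed = 1L) {
  stopifnot(m >= 2, target %in% names(data))
  y <- as.numeric(data[[target]])
  miss <- is.na(y)
  X <- build_predictor_matrix(data, predictors, extra)
  obs <- which(!miss)
  if (length(obs) < donors) stop("fewer complete cases than donors",
                                 call. = FALSE)
  if (length(obs) <= ncol(X))
    stop("fewer complete cases than predictors", call. = FALSE)
  draws <- matrix(NA_real_, nrow = sum(miss), ncol = m)
  if (any(miss)) {
    for (i in seq_len(m)) {
      with_stream(stream_seed(seed, "imp", i), {
        draws[, i] <- draw_pmm(X[obs, , drop = FALSE], y[obs],
                               X[miss, , drop = FALSE], donors)
      })
    }
  }
  new_imputations(data, m, seed, stats::setNames(
    list(list(method = "pmm", miss = which(miss), draws = draws)), target))
}

#' Specify one variable's imputation model for chained equations
#'
#' @param method `"polytomous"` (categorical), `"logistic"` (binary, fitted
#'   as a 2-category polytomous model), `"pmm"` or `"normal"` (continuous).
#' @param predictors Covariate columns used as predictors.
#' @param extra Optional numeric predictor matrix (e.g. bin methylation).
#' @param ridge Ridge penalty for the categorical methods.
#' @param donors Donor-pool size for `"pmm"`.
#' @export
imputation_spec <- function(method = c("polytomous", "logistic", "pmm",
                                       "normal"),
                            predictors, extra = NULL, ridge = 1e-5,
                            donors = 5) {
  structure(list(method = match.arg(method), predictors = predictors,
                 extra = extra, ridge = ridge, donors = donors),
            class = "imputation_spec")
}

#' Chained-equations multiple imputation over several incomplete covariates
#'
#' Missing cells are initialized by random draws from each variable's
#' observed marginal; the engine then cycles over the incomplete variables
#' in order of increasing missingness, re-imputing each from the current
#' completed values of its predictors, for `n_cycles` cycles.  The whole
#' process runs independently `m` times.  Auxiliary variables may appear as
#' predictors in imputation models without entering any analysis model.
#'
#' @param data Covariate tibble; every column with missing values must have
#'   a spec.
#' @param specs Named list of [imputation_spec()]s, one per incomplete
#'   variable.
#' @param m Number of imputations.
#' @param n_cycles Chained-equation cycles per imputation (default 10).
#' @param seed Integer seed.
#' @return An `imputations` object covering all incomplete variables.
#' @export
impute_chained <- function(data, specs, m = 100, n_cycles = 10, seed = 1L) {
  stopifnot(m >= 2, n_cycles >= 1)
  incomplete <- names(data)[vapply(data, anyNA, logical(1))]
  missing_spec <- setdiff(incomplete, names(specs))
  if (length(missing_spec))
    stop("no imputation spec for incomplete variable(s): ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  # visit order: increasing missingness
  n_mis <- vapply(incomplete, function(v) sum(is.na(data[[v]])), integer(1))
  visit <- incomplete[order(n_mis)]
  miss_idx <- lapply(data[visit], function(x) which(is.na(x)))
  targets <- lapply(visit, function(v) {
    list(method = specs[[v]]$method, miss = miss_idx[[v]],
         draws = if (specs[[v]]$method %in% c("pmm", "normal"))
           matrix(NA_real_, length(miss_idx[[v]]), m)
         else matrix(NA_character_, length(miss_idx[[v]]), m))
  })
  names(targets) <- visit

  for (i in seq_len(m)) {
    with_stream(stream_seed(seed, "chain", i), {
      cur <- data
      for (v in visit) { # initialize from observed marginals
        obs_vals <- cur[[v]][!is.na(cur[[v]])]
        cur[[v]][miss_idx[[v]]] <- sample(obs_vals, length(miss_idx[[v]]),
                                          replace = TRUE)
      }
      for (cycle in seq_len(n_cycles)) {
        for (v in visit) {
          sp <- specs[[v]]
          mi <- miss_idx[[v]]
          if (!length(mi)) next
          X <- build_predictor_matrix(cur, sp$predictors, sp$extra)
          obs <- setdiff(seq_len(nrow(cur)), mi)
          yv <- cur[[v]]
          imputed <- switch(
            sp$method,
            polytomous = ,
            logistic = draw_categorical(X[obs, , drop = FALSE],
                                        factor(yv[obs]),
                                        X[mi, , drop = FALSE], sp$ridge),
            pmm = draw_pmm(X[obs, , drop = FALSE], as.numeric(yv[obs]),
                           X[mi, , drop = FALSE], sp$donors),
            normal = draw_normal(X[obs, , drop = FALSE], as.numeric(yv[obs]),
                                 X[mi, , drop = FALSE])
          )
          if (is.factor(yv)) {
            cur[[v]][mi] <- factor(imputed, levels = levels(yv))
          } else {
            cur[[v]][mi] <- imputed
          }
        }
      }
      for (v in visit) {
        vals <- cur[[v]][miss_idx[[v]]]
        targets[[v]]$draws[, i] <- if (is.factor(vals)) as.character(vals)
          else as.numeric(vals)
      }
    })
  }
  new_imputations(data, m, seed, targets)
}

#' Extract completed datasets from an imputation run
#'
#' @param imputations An `imputations` object.
#' @param i Which imputation to complete; `NULL` returns the list of all
#'   `m` completed tibbles.
#' @return A completed tibble (or list of them); originally observed cells
#'   are identical to the input in every completion.
#' @export
complete_datasets <- function(imputations, i = NULL) {
  stopifnot(inherits(imputations, "imputations"))
  if (is.null(i))
    return(lapply(seq_len(imputations$m),
                  function(k) complete_datasets(imputations, k)))
  stopifnot(i >= 1, i <= imputations$m)
  out <- imputations$data
  for (v in names(imputations$targets)) {
    tg <- imputations$targets[[v]]
    if (!length(tg$miss)) next
    vals <- tg$draws[, i]
    if (is.factor(out[[v]])) {
      out[[v]][tg$miss] <- factor(vals, levels = levels(out[[v]]))
    } else {
      out[[v]][tg$miss] <- vals
    }
  }
  out
}

#' @export
print.imputations <- function(x, ...) {
  cat("<imputations> m =", x$m, "\n")
  for (v in names(x$targets))
    cat(" ", v, ": ", length(x$targets[[v]]$miss), " missing cells (",
        x$targets[[v]]$method, ")\n", sep = "")
  invisible(x)
}

new_imputations <- function(data, m, seed, targets) {
  structure(list(data = data, m = m, seed = seed, targets = targets),
            class = "imputations")
}

# reference-coded design matrix with intercept; `extra` columns appended
build_predictor_matrix <- function(data, predictors, extra = NULL) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  for (v in predictors) {
    x <- data[[v]]
    if (is.null(x)) stop("predictor '", v, "' not found", call. = FALSE)
    if (is.factor(x) || is.character(x)) {
      f <- if (is.factor(x)) x else factor(x)
      for (lv in levels(f)[-1L]) {
        cols[[paste0(v, lv)]] <- as.numeric(f == lv)
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == n)
    X <- cbind(X, extra)
  }
  X
}

# one proper draw of categories for the missing cases: bootstrap the
# complete cases (keeping every observed category, <= 10 redraws), fit the
# ridge multinomial, sample from fitted probabilities
draw_categorical <- function(Xobs, yobs, Xmis, ridge, max_retry = 10L) {
  yobs <- droplevels(factor(yobs))
  draw_categorical_core(Xobs, as.integer(yobs), length(levels(yobs)),
                        levels(yobs), Xmis, ridge, max_retry)
}

# sample one category per row of a probability matrix
draw_from_probs <- function(pr, lev) {
  K <- length(lev)
  u <- runif(nrow(pr))
  cum <- pr %*% upper.tri(diag(K), diag = TRUE)
  lev[pmin(rowSums(u > cum) + 1L, K)]
}

# codes-based core so callers can hoist the factor bookkeeping out of the
# per-bin / per-imputation loop
draw_categorical_core <- function(Xobs, codes, K, lev, Xmis, ridge,
                                  max_retry = 10L) {
  n_obs <- nrow(Xobs)
  if (K == 1L) return(rep(lev, nrow(Xmis)))
  if (ncol(Xobs) >= n_obs)
    stop("imputation model has as many predictors (", ncol(Xobs),
         ") as complete cases (", n_obs, "); use smaller bins",
         call. = FALSE)
  for (attempt in seq_len(max_retry)) {
    bs <- sample.int(n_obs, n_obs, replace = TRUE)
    if (length(unique(codes[bs])) == K) {
      fit <- fit_multinom_ridge(Xobs[bs, , drop = FALSE], codes[bs], K,
                                ridge = ridge)
      pr <- predict_multinom(fit, Xmis)
      u <- runif(nrow(Xmis))
      cum <- pr %*% upper.tri(diag(K), diag = TRUE)
      idx <- rowSums(u > cum) + 1L
      return(lev[pmin(idx, K)])
    }
  }
  stop("bootstrap resample lost an observed category after ", max_retry,
       " attempts; too few cases in some category", call. = FALSE)
}

# one proper PMM draw: Bayesian-bootstrap-weighted fit, nearest-donor match
draw_pmm <- function(Xobs, yobs, Xmis, donors) {
  w <- rexp(nrow(Xobs))
  fit_b <- stats::lm.wfit(Xobs, yobs, w)
  fit_hat <- stats::lm.fit(Xobs, yobs)
  yhat_obs <- drop(Xobs %*% fit_hat$coefficients)
  yhat_mis <- drop(Xmis %*% fit_b$coefficients)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d, runif(length(d)))[seq_len(donors)]
    yobs[sample(pool, 1L)]
  }, numeric(1))
}

# one proper normal-model draw: bootstrap fit plus residual noise
draw_normal <- function(Xobs, yobs, Xmis) {
  n_obs <- nrow(Xobs)
  bs <- sample.int(n_obs, n_obs, replace = TRUE)
  fit <- stats::lm.fit(Xobs[bs, , drop = FALSE], yobs[bs])
  sigma <- sqrt(sum(fit$residuals^2) /
                  max(1L, n_obs - ncol(Xobs)))
  drop(Xmis %*% fit$coefficients) + rnorm(nrow(Xmis), 0, sigma)
}
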