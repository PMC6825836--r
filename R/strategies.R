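#' Partition CpG sites into random bins of fixed size
#'
#' Sites are shuffled under the seed and cut into consecutive chunks of
#' `bin_size` (the last bin may be smaller), so the bins partition the site
#' set and the bin count is `ceiling(N / bin_size)` — e.g. 482,739 sites
#' give 3,219 bins of 150 or 10,728 bins of 45.
#'
#' @param site_ids Character vector of site IDs.
#' @param bin_size Maximum sites per bin (`>= 1`).
#' @param seed Integer seed for the shuffle.
#' @return A `bin_scheme` object.
#' @export
#' @examples
#' make_random_bins(paste0("cg", 1:10), bin_size = 4, seed = 1)
make_random_bins <- function(site_ids, bin_size, seed = 1L) {
  stopifnot(bin_size >= 1)
  if (!length(site_ids)) stop("empty site list", call. = FALSE)
  shuffled <- with_stream(stream_seed(seed, "bins"),
                          sample(site_ids, length(site_ids)))
  groups <- ceiling(seq_along(shuffled) / bin_size)
  new_bin_scheme("random_bins", unname(split(shuffled, groups)),
                 always_included = character(), bin_size = bin_size,
                 seed = seed)
}

#' Random bins that all contain a selected site set
#'
#' The non-selected sites are shuffled and chunked into groups of
#' `bin_size - |selected|`; each bin is the selected set plus one chunk,
#' giving `ceiling((N - s) / (bin_size - s))` bins.
#'
#' @inheritParams make_random_bins
#' @param selected Site IDs included in every bin (fewer than `bin_size`).
#' @export
make_wu_bins <- function(site_ids, selected, bin_size, seed = 1L) {
  stopifnot(bin_size >= 1)
  if (!length(site_ids)) stop("empty site list", call. = FALSE)
  selected <- intersect(selected, site_ids)
  if (length(selected) >= bin_size)
    stop(length(selected), " selected sites do not fit in bins of ",
         bin_size, "; increase bin_size", call. = FALSE)
  rest <- setdiff(site_ids, selected)
  if (!length(rest)) {
    bins <- list(selected)
  } else {
    shuffled <- with_stream(stream_seed(seed, "bins"),
                            sample(rest, length(rest)))
    groups <- ceiling(seq_along(shuffled) / (bin_size - length(selected)))
    bins <- lapply(unname(split(shuffled, groups)),
                   function(chunk) c(selected, chunk))
  }
  new_bin_scheme("wu_bins", bins, always_included = selected,
                 bin_size = bin_size, seed = seed)
}

new_bin_scheme <- function(strategy, bins, always_included, bin_size, seed) {
  structure(list(strategy = strategy, bins = bins,
                 always_included = always_included, bin_size = bin_size,
                 seed = seed),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("<bin_scheme> ", x$strategy, ": ", length(x$bins), " bins (size <= ",
      x$bin_size, ", ", length(x$always_included),
      " sites in every bin)\n", sep = "")
  invisible(x)
}

#' Number of bins in a scheme
#' @param scheme A `bin_scheme`.
#' @export
n_bins <- function(scheme) length(scheme$bins)

#' Select imputation predictors: all Bonferroni-significant C-C sites
#'
#' The naive strategy's site set: every site significant in the
#' complete-case EWAS at the Bonferroni threshold, in ascending p order.
#' An empty selection is allowed (the strategy then imputes from age and
#' sex only).
#'
#' @param cc_results Complete-case EWAS table (from [run_ewas()]).
#' @param alpha Family-wise error level.
#' @param n_tests Bonferroni denominator.
#' @return Character vector of site IDs.
#' @export
select_sites_naive <- function(cc_results, alpha = 0.05, n_tests = NULL) {
  significant_sites(cc_results, alpha = alpha, n_tests = n_tests)
}

#' Select imputation predictors by forward-stepwise BIC (Wu method)
#'
#' Candidates are the `top_k` sites ranked by the complete-case EWAS
#' (ascending minimum smoking p-value, ties by site ID).  Starting from the
#' base multinomial model smoking ~ age + sex fitted on the complete cases,
#' the candidate giving the largest BIC decrease is added repeatedly until
#' no candidate decreases BIC (BIC = -2 log L + p log n over all model
#' parameters).
#'
#' @param cc_results Complete-case EWAS table.
#' @param methylation Standardized methylation matrix aligned with
#'   `covariates` rows.
#' @param covariates Covariate tibble (rows with missing smoking are
#'   dropped; selection uses complete cases only).
#' @param top_k Number of top-ranked candidate sites (default 100).
#' @return Character vector of selected site IDs, in addition order.
#' @export
select_sites_wu <- function(cc_results, methylation, covariates,
                            top_k = 100) {
  methylation <- as_methylation_matrix(methylation)
  if (top_k == 0) return(character())
  p_min <- pmin(cc_results$p_former, cc_results$p_current, na.rm = TRUE)
  ranking <- cc_results$site_id[order(p_min, cc_results$site_id)]
  candidates <- head(ranking, top_k)

  keep <- stats::complete.cases(covariates[, c("age", "sex", "smoking")])
  cc <- covariates[keep, , drop = FALSE]
  y <- droplevels(factor(cc$smoking))
  K <- nlevels(y)
  codes <- as.integer(y)
  meth_cc <- t(methylation[candidates, keep, drop = FALSE])

  Xbase <- build_predictor_matrix(cc, c("age", "sex"))
  selected <- character()
  bic_cur <- multinom_bic(Xbase, codes, K)
  Xcur <- Xbase
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    bics <- vapply(remaining, function(s) {
      multinom_bic(cbind(Xcur, meth_cc[, s, drop = FALSE]), codes, K)
    }, numeric(1))
    best <- which.min(bics)
    if (bics[best] >= bic_cur) break
    site <- remaining[best]
    selected <- c(selected, site)
    Xcur <- cbind(Xcur, meth_cc[, site, drop = FALSE])
    bic_cur <- bics[best]
  }
  selected
}

#' Run one imputation strategy end to end
#'
#' The unit the simulation study compares: build the strategy's bin scheme,
#' impute missing smoking per bin from age + sex + the bin's methylation
#' (`m` imputations each), fit the EWAS at every site assigned to the bin
#' on each completed dataset, pool by Rubin's rules, and concatenate the
#' per-bin tables so every site appears exactly once.
#'
#' Strategies: `"complete_case"` (no imputation; rows with missing smoking
#' dropped), `"separate"` (one singleton bin per site), `"random_bins"`
#' (fixed-size random bins), `"naive"` (one model using all
#' Bonferroni-significant complete-case sites; EWAS at every site),
#' `"wu"` (one model using the forward-stepwise BIC selection from the top
#' `top_k` complete-case sites), `"wu_bins"` (random bins each augmented
#' with the Wu selection).
#'
#' @param methylation Standardized sites x individuals matrix.
#' @param covariates Covariate tibble aligned to the columns; `smoking` may
#'   contain `NA`.
#' @param strategy One of the six strategy names.
#' @param bin_size Bin size for the binned strategies.
#' @param m Number of imputations per bin (default 20).
#' @param alpha Family-wise error level.
#' @param ridge Ridge penalty for the imputation models.
#' @param boot If `TRUE`, each imputation refits the imputation model on a
#'   bootstrap resample of the complete cases (proper MI).  The default
#'   `FALSE` fits once per bin and draws every imputation from the fitted
#'   probabilities, matching the polytomous-regression imputation the
#'   strategies were evaluated with; its pooled SEs are slightly smaller.
#' @param top_k Candidate-set size for the Wu selection.
#' @param seed Integer seed; bin `b`, imputation `i` uses the sub-stream
#'   `stream_seed(seed, "bin", b, "imp", i)`, so results are independent of
#'   execution order.
#' @param max_separate Guard for `"separate"`: refuse more sites than this
#'   unless `force = TRUE` (one imputation run per site is the documented
#'   cost of that strategy).
#' @param force Override the `"separate"` guard.
#' @return A `pooled_ewas` tibble (columns as in [run_ewas()]) with
#'   attributes `strategy`, `m`, `n_bins` and `selected` (the selection
#'   used, for naive/wu/wu_bins).
#' @export
#' @examples
#' cohort <- simulate_cohort(150, seed = 1)
#' sim <- simulate_methylation(cohort, 60, 6, seed = 1)
#' miss <- apply_missingness(cohort, mm1(), seed = 1)
#' run_strategy(sim$methylation, miss, "random_bins", bin_size = 15, m = 5,
#'              seed = 1)
run_strategy <- function(methylation, covariates,
                         strategy = c("complete_case", "separate",
                                      "random_bins", "naive", "wu",
                                      "wu_bins"),
                         bin_size = NULL, m = 20, alpha = 0.05,
                         ridge = 1e-5, boot = FALSE, top_k = 100,
                         seed = 1L, max_separate = 50000L, force = FALSE) {
  strategy <- match.arg(strategy)
  methylation <- as_methylation_matrix(methylation)
  stopifnot(ncol(methylation) == nrow(covariates))
  site_ids <- rownames(methylation)
  n_tests <- length(site_ids)

  if (strategy == "complete_case") {
    res <- run_ewas(methylation, covariates, alpha = alpha,
                    n_tests = n_tests)
    return(new_pooled_ewas(tibble::as_tibble(res), strategy = strategy,
                           m = 1L, alpha = alpha, n_tests = n_tests))
  }

  needs_cc <- strategy %in% c("naive", "wu", "wu_bins")
  selected <- character()
  if (needs_cc) {
    cc_res <- run_ewas(methylation, covariates, alpha = alpha,
                       n_tests = n_tests)
    selected <- switch(strategy,
      naive = select_sites_naive(cc_res, alpha = alpha, n_tests = n_tests),
      wu = ,
      wu_bins = select_sites_wu(cc_res, methylation, covariates,
                                top_k = top_k))
  }

  scheme <- switch(strategy,
    separate = {
      if (n_tests > max_separate && !force)
        stop("'separate' would run ", n_tests, " imputation procedures; ",
             "set force = TRUE to accept the cost", call. = FALSE)
      new_bin_scheme("separate", as.list(site_ids),
                     always_included = character(), bin_size = 1L,
                     seed = seed)
    },
    random_bins = {
      stopifnot(!is.null(bin_size))
      make_random_bins(site_ids, bin_size, seed = seed)
    },
    naive = ,
    wu = new_bin_scheme(strategy, list(selected),
                        always_included = selected,
                        bin_size = length(selected), seed = seed),
    wu_bins = {
      stopifnot(!is.null(bin_size))
      make_wu_bins(site_ids, selected, bin_size, seed = seed)
    })

  # for the one-model strategies the single imputation serves the EWAS at
  # every site; for binned strategies each bin's imputations serve only the
  # sites assigned to that bin
  ewas_all_sites <- strategy %in% c("naive", "wu")
  out <- run_binned_mi(methylation, covariates, scheme, m = m,
                       ridge = ridge, seed = seed,
                       ewas_all_sites = ewas_all_sites, boot = boot)
  out <- out[match(site_ids, out$site_id), , drop = FALSE]
  out$significant <- pmin(out$p_former, out$p_current, na.rm = TRUE) <
    alpha / n_tests
  new_pooled_ewas(out, strategy = strategy, m = m, alpha = alpha,
                  n_tests = n_tests, n_bins = length(scheme$bins),
                  selected = selected)
}

# impute per bin and pool the per-imputation EWAS fits
run_binned_mi <- function(methylation, covariates, scheme, m, ridge, seed,
                          ewas_all_sites = FALSE, boot = FALSE) {
  miss <- is.na(covariates$smoking)
  obs <- which(!miss)
  y <- covariates$smoking
  yobs <- droplevels(factor(y[obs]))
  codes <- as.integer(yobs)
  lev <- levels(yobs)
  K <- length(lev)
  tY <- t(methylation)                           # individuals x sites
  X_base <- build_predictor_matrix(covariates, c("age", "sex"))
  completed <- covariates
  results <- vector("list", length(scheme$bins))
  for (b in seq_along(scheme$bins)) {
    bin_sites <- scheme$bins[[b]]
    ewas_sites <- if (ewas_all_sites) rownames(methylation) else bin_sites
    Y_full <- tY[, ewas_sites, drop = FALSE]
    ns <- length(ewas_sites)
    bf <- sf <- bc <- sc <- matrix(NA_real_, m, ns)
    df_com <- NA_real_
    if (!any(miss)) {
      design <- build_ewas_design(covariates)
      fit <- fit_ewas_matrix(Y_full, design)
      bf <- matrix(fit$beta_former, m, ns, byrow = TRUE)
      sf <- matrix(fit$se_former, m, ns, byrow = TRUE)
      bc <- matrix(fit$beta_current, m, ns, byrow = TRUE)
      sc <- matrix(fit$se_current, m, ns, byrow = TRUE)
      df_com <- fit$df
    } else {
      X_imp <- if (length(bin_sites))
        cbind(X_base, tY[, bin_sites, drop = FALSE]) else X_base
      X_imp_obs <- X_imp[obs, , drop = FALSE]
      X_imp_mis <- X_imp[miss, , drop = FALSE]
      pr <- NULL
      if (!boot && K > 1L) {
        # one fit per bin on the observed cases; each imputation then
        # draws categories from the fitted probabilities (the behaviour
        # of mice's polyreg, which the strategies were evaluated with)
        if (ncol(X_imp_obs) >= nrow(X_imp_obs))
          stop("imputation model has as many predictors (",
               ncol(X_imp_obs), ") as complete cases (", nrow(X_imp_obs),
               "); use smaller bins", call. = FALSE)
        fit <- fit_multinom_ridge(X_imp_obs, codes, K, ridge = ridge)
        pr <- predict_multinom(fit, X_imp_mis)
      }
      for (i in seq_len(m)) {
        drawn <- with_stream(stream_seed(seed, "bin", b, "imp", i), {
          if (boot || K == 1L)
            draw_categorical_core(X_imp_obs, codes, K, lev, X_imp_mis,
                                  ridge)
          else
            draw_from_probs(pr, lev)
        })
        completed$smoking[miss] <- factor(drawn, levels = levels(y))
        design <- build_ewas_design(completed)
        fit <- fit_ewas_matrix(Y_full, design)
        bf[i, ] <- fit$beta_former
        sf[i, ] <- fit$se_former
        bc[i, ] <- fit$beta_current
        sc[i, ] <- fit$se_current
        df_com <- fit$df
      }
    }
    results[[b]] <- pool_smoking_fits(ewas_sites, bf, sf, bc, sc, df_com)
    if (ewas_all_sites) break # one model serves all sites
  }
  dplyr::bind_rows(results[!vapply(results, is.null, logical(1))])
}
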