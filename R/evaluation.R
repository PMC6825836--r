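#' True-positive and false-positive percentages
#'
#' "True" sites are those significant in the EWAS on the complete
#' (no-missingness) data.  The true-positive percentage is the share of
#' true sites a method recovered; the false-positive percentage is the
#' share of the method's significant sites that are not true (a false
#' discovery proportion), reported `NaN` when the method found nothing.
#'
#' @param found Character vector (or pooled EWAS table) of the method's
#'   significant sites.
#' @param truth Character vector (or pooled EWAS table) of the
#'   complete-data significant sites; must be non-empty.
#' @return Tibble with `tp_pct` and `fp_pct`.
#' @export
#' @examples
#' tp_fp_rates(c("a", "b", "d", "e"), c("a", "b", "c"))  # 66.7%, 50%
tp_fp_rates <- function(found, truth) {
  if (inherits(found, "pooled_ewas")) found <- significant_sites(found)
  if (inherits(truth, "pooled_ewas")) truth <- significant_sites(truth)
  if (!length(truth)) stop("empty truth set", call. = FALSE)
  tp <- 100 * length(intersect(found, truth)) / length(truth)
  fp <- if (!length(found)) NaN else
    100 * length(setdiff(found, truth)) / length(found)
  tibble::tibble(tp_pct = tp, fp_pct = fp)
}

#' Per-group mean bias of a method against the complete-data truth
#'
#' Bias per site is the method's coefficient minus the complete-data
#' ("truth") coefficient.  Sites are grouped as in the detailed bias
#' tables: (1) the selection used in the imputation model (the C-C
#' significant set for the naive strategy, the BIC selection for Wu);
#' (2) sites significant in the complete data but not selected; (3) all
#' other sites — each split by the sign of the truth coefficient.
#'
#' @param method_results Pooled EWAS tibble for the method.
#' @param truth_results Complete-data EWAS tibble on the same sites.
#' @param selected Site IDs used in the method's imputation model.
#' @param term `"former"` (default, as in the published tables) or
#'   `"current"`.
#' @param alpha,n_tests Significance rule for the truth set.
#' @return Tibble with one row per (group, sign): `n`, `mean_beta`,
#'   `mean_se`, `mean_bias`, `sd_bias`.
#' @export
bias_table <- function(method_results, truth_results,
                       selected = character(), term = "former",
                       alpha = 0.05, n_tests = NULL) {
  stopifnot(term %in% c("former", "current"))
  if (!identical(sort(method_results$site_id), sort(truth_results$site_id)))
    stop("method and truth tables cover different sites", call. = FALSE)
  n_tests <- n_tests %||% attr(truth_results, "n_tests") %||%
    nrow(truth_results)
  truth_sig <- significant_sites(truth_results, alpha = alpha,
                                 n_tests = n_tests)
  bcol <- paste0("beta_", term)
  scol <- paste0("se_", term)
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(method_results), "site_id",
                  beta = dplyr::all_of(bcol), se = dplyr::all_of(scol)),
    dplyr::select(tibble::as_tibble(truth_results), "site_id",
                  beta_truth = dplyr::all_of(bcol)),
    by = "site_id")
  joined |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$site_id %in% selected ~ "selected",
        .data$site_id %in% truth_sig ~ "true_not_selected",
        TRUE ~ "other"),
      sign = ifelse(.data$beta_truth > 0, "positive", "negative"),
      bias = .data$beta - .data$beta_truth) |>
    dplyr::group_by(.data$group, .data$sign) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_beta = mean(.data$beta),
      mean_se = mean(.data$se),
      mean_bias = mean(.data$bias),
      sd_bias = sd(.data$bias),
      .groups = "drop")
}

#' Label a strategy configuration for the simulation study
#'
#' @param strategy Strategy name accepted by [run_strategy()].
#' @param bin_size Bin size for the binned strategies.
#' @param ... Further arguments forwarded to [run_strategy()]
#'   (e.g. `top_k`).
#' @export
strategy_spec <- function(strategy, bin_size = NULL, ...) {
  structure(list(strategy = strategy, bin_size = bin_size,
                 args = list(...)), class = "strategy_spec")
}

#' Replicate-level simulation study of the imputation strategies
#'
#' For each repeat: simulate a cohort and methylation matrix, run the
#' complete-data EWAS to define the truth, induce missingness under each
#' mechanism, run every strategy, and record its performance.  The result
#' is a tidy table with one row per (repeat, mechanism, strategy).
#'
#' @param n Individuals per replicate.
#' @param n_sites,n_true Sites and smoking-associated sites per replicate.
#' @param mechanisms List of [mm_mechanism()]s.
#' @param strategies Named list of [strategy_spec()]s.
#' @param repeats Number of replicates.
#' @param m Imputations per bin.
#' @param alpha Family-wise error level.
#' @param seed Integer base seed; repeat `r` derives every stage from
#'   `stream_seed(seed, "rep", r, ...)`.
#' @param include_complete Also emit one `complete_data` reference row per
#'   repeat (TP 100, FP 0 by construction).
#' @param keep_bias Attach a [bias_table()] list-column (`bias`).
#' @param effect_range Planted effect-magnitude range (SD units).
#' @return Tibble with columns `rep`, `mechanism`, `strategy`,
#'   `n_significant`, `tp_pct`, `fp_pct`, `mean_se`, `sd_se`, `n_true_sites`
#'   (size of the truth set; repeats with an empty truth set have `NA`
#'   rates and are flagged by `truth_empty`), plus `bias` if requested.
#' @export
run_simulation_study <- function(n = 464, n_sites = 2000, n_true = 40,
                                 mechanisms = list(mm1()),
                                 strategies = list(
                                   complete_case = strategy_spec("complete_case")),
                                 repeats = 10, m = 20, alpha = 0.05,
                                 seed = 1L, include_complete = TRUE,
                                 keep_bias = FALSE,
                                 effect_range = c(0.15, 0.60)) {
  rows <- list()
  for (r in seq_len(repeats)) {
    cohort <- simulate_cohort(n, seed = stream_seed(seed, "rep", r))
    sim <- simulate_methylation(cohort, n_sites, n_true,
                                effect_range_former = effect_range,
                                effect_range_current = effect_range,
                                seed = stream_seed(seed, "rep", r))
    truth_res <- run_ewas(sim$methylation, cohort, alpha = alpha)
    truth_sig <- significant_sites(truth_res)
    truth_empty <- length(truth_sig) == 0L
    if (include_complete) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = r, mechanism = "none", strategy = "complete_data",
        n_significant = length(truth_sig),
        tp_pct = if (truth_empty) NA_real_ else 100,
        fp_pct = if (truth_empty) NA_real_ else 0,
        mean_se = mean(truth_res$se_former),
        sd_se = sd(truth_res$se_former),
        n_true_sites = length(truth_sig), truth_empty = truth_empty)
    }
    for (mech in mechanisms) {
      miss <- apply_missingness(cohort, mech,
                                seed = stream_seed(seed, "rep", r))
      for (lab in names(strategies)) {
        sp <- strategies[[lab]]
        res <- do.call(run_strategy, c(
          list(methylation = sim$methylation, covariates = miss,
               strategy = sp$strategy, bin_size = sp$bin_size, m = m,
               alpha = alpha,
               seed = stream_seed(seed, "rep", r, "strat", lab)),
          sp$args))
        found <- significant_sites(res)
        rates <- if (truth_empty) tibble::tibble(tp_pct = NA_real_,
                                                 fp_pct = NA_real_)
          else tp_fp_rates(found, truth_sig)
        row <- tibble::tibble(
          rep = r, mechanism = mech$name, strategy = lab,
          n_significant = length(found),
          tp_pct = rates$tp_pct, fp_pct = rates$fp_pct,
          mean_se = mean(res$se_former, na.rm = TRUE),
          sd_se = sd(res$se_former, na.rm = TRUE),
          n_true_sites = length(truth_sig), truth_empty = truth_empty)
        if (keep_bias) {
          row$bias <- list(bias_table(res, truth_res,
                                      selected = attr(res, "selected"),
                                      alpha = alpha))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise a simulation study across repeats
#'
#' Means of the per-repeat metrics by (mechanism, strategy); `NaN`
#' false-positive rates (repeats with no discoveries) and repeats with an
#' empty truth set are excluded from the averages, with counts reported.
#'
#' @param study Output of [run_simulation_study()].
#' @return One row per (mechanism, strategy) with mean metrics.
#' @export
summarise_study <- function(study) {
  study |>
    dplyr::filter(!.data$truth_empty) |>
    dplyr::group_by(.data$mechanism, .data$strategy) |>
    dplyr::summarise(
      repeats = dplyr::n(),
      n_significant = mean(.data$n_significant),
      tp_pct = mean(.data$tp_pct),
      fp_pct = mean(.data$fp_pct[!is.nan(.data$fp_pct)]),
      n_zero_discovery = sum(is.nan(.data$fp_pct)),
      mean_se = mean(.data$mean_se),
      sd_se = mean(.data$sd_se),
      .groups = "drop")
}
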