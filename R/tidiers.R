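#' Tidy a pooled EWAS table into one row per coefficient
#'
#' @param x A `pooled_ewas` tibble.
#' @param ... Unused.
#' @return Tibble with `site_id`, `term` (former/current), `estimate`,
#'   `std.error`, `df`, `p.value`, `significant`.
#' @export
tidy.pooled_ewas <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("site_id", dplyr::matches("^(beta|se|df|p)_"),
                  "significant") |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(beta|se|df|p)_(former|current)$"),
      names_to = c(".value", "term"),
      names_pattern = "(beta|se|df|p)_(former|current)") |>
    dplyr::rename(estimate = "beta", std.error = "se", p.value = "p")
}

#' One-row summary of a pooled EWAS
#'
#' @param x A `pooled_ewas` tibble.
#' @param ... Unused.
#' @return Tibble with the strategy, number of imputations and bins, site
#'   and significant-site counts, the Bonferroni threshold and the mean
#'   former-smoking SE.
#' @export
glance.pooled_ewas <- function(x, ...) {
  tibble::tibble(
    strategy = attr(x, "strategy") %||% NA_character_,
    m = attr(x, "m") %||% NA_integer_,
    n_bins = attr(x, "n_bins") %||% NA_integer_,
    n_sites = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    bonferroni = (attr(x, "alpha") %||% 0.05) /
      (attr(x, "n_tests") %||% nrow(x)),
    mean_se_former = mean(x$se_former, na.rm = TRUE))
}

#' Manhattan-style plot of a pooled EWAS
#'
#' Plots -log10 of each site's minimum smoking p-value against site index,
#' with the Bonferroni threshold as a dashed line and significant sites
#' highlighted.
#'
#' @param object A `pooled_ewas` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pooled_ewas <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  n_tests <- attr(object, "n_tests") %||% nrow(object)
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(index = dplyr::row_number(),
                  p_min = pmin(.data$p_former, .data$p_current,
                               na.rm = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index,
                                  y = -log10(.data$p_min),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha / n_tests),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "site index",
                  y = expression(-log[10] * "(min smoking p)"),
                  title = attr(object, "strategy")) +
    ggplot2::theme_minimal()
}

#' Compare strategies across replicates of a simulation study
#'
#' Boxplots of the per-repeat mean standard error by strategy, plus points
#' for the per-repeat true-positive percentages, faceted by metric.
#'
#' @param study Output of [run_simulation_study()].
#' @return A ggplot object.
#' @export
plot_performance <- function(study) {
  long <- study |>
    dplyr::select("rep", "mechanism", "strategy", "tp_pct", "fp_pct",
                  "mean_se") |>
    tidyr::pivot_longer(c("tp_pct", "fp_pct", "mean_se"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$value,
                                     colour = .data$mechanism)) +
    ggplot2::geom_boxplot(outlier.size = 0.6,
                          position = ggplot2::position_dodge(width = 0.7)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
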