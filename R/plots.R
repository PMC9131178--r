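# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate with censoring ticks.
#'
#' @param object A `"km_curve"` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object[, c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$n_censor > 0),
      shape = 3
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot a stratified survival analysis
#'
#' Kaplan-Meier curves of the low- and high-ADI groups with the log-rank
#' p-value and hazard ratio in the subtitle.
#'
#' @param object An `"adi_survival"` object from [stratify_survival()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot adi_survival
#' @export
autoplot.adi_survival <- function(object, ...) {
  km <- object$km
  starts <- km |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(starts, km[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time", y = "Overall survival", color = "ADI group",
      subtitle = sprintf("log-rank p = %.3g; HR = %.2f (95%% CI %.2f-%.2f)",
                         object$logrank$p, object$cox$hr,
                         object$cox$ci_low, object$cox$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-patient tissue composition
#'
#' @param scores Patient score tibble from [aggregate_patient_scores()].
#' @return A ggplot of stacked class proportions per patient.
#' @export
plot_composition <- function(scores) {
  long <- scores |>
    dplyr::select("patient_id", dplyr::starts_with("prop_")) |>
    tidyr::pivot_longer(-"patient_id", names_to = "class",
                        values_to = "proportion",
                        names_prefix = "prop_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient_id,
                                     y = .data$proportion,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Tile proportion", fill = "Tissue class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano-style plot of group comparisons
#'
#' @param comparison Result of [compare_groups()].
#' @return A ggplot of mean difference vs -log10 q.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$statistic,
                               y = -log10(.data$q),
                               color = .data$q < 0.05)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "Mean difference (high - low)",
                  y = expression(-log[10] ~ q), color = "q < 0.05") +
    ggplot2::theme_minimal()
}
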