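#' Stratify patients by ADI and compare overall survival
#'
#' The full prognostic analysis for one (sub)cohort: dichotomize the ADI
#' score (maximally selected cutpoint by default, median split as the
#' alternative), estimate Kaplan-Meier curves per group, test the
#' difference by log-rank, and estimate the high-vs-low hazard ratio with
#' a univariate Cox fit.
#'
#' @param scores Patient-level tibble with `patient_id` and the score
#'   column (e.g. from [aggregate_patient_scores()] or
#'   [simulate_cohort()]).
#' @param survival_data Tibble with `patient_id`, `time`, `event`; NULL if
#'   `scores` already carries those columns.
#' @param score Score column name (default `"adi"`).
#' @param method `"cutpoint"` (default) or `"median"`.
#' @param minprop Minimum group fraction for the cutpoint search.
#' @param subgroup Optional logical expression evaluated in the joined
#'   table to restrict the analysis (e.g. `sex == "male"`).
#' @return Object of class `"adi_survival"`: `data` (joined table with
#'   `group`), `method`, `cutpoint` (NA for median split), `km` (stacked
#'   [km_curve()] tibble with a `group` column), `logrank`, `cox`,
#'   `n` and `n_event` per group, and `reliable` (FALSE when a group has
#'   fewer than 2 events).
#' @export
#' @examples
#' coh <- simulate_cohort(200, seed = 11)
#' res <- stratify_survival(coh, method = "median")
#' glance(res)
stratify_survival <- function(scores, survival_data = NULL, score = "adi",
                              method = c("cutpoint", "median"),
                              minprop = 0.1, subgroup = NULL) {
  method <- match.arg(method)
  df <- tibble::as_tibble(scores)
  if (!is.null(survival_data)) {
    df <- dplyr::inner_join(df, tibble::as_tibble(survival_data),
                            by = "patient_id")
  }
  sub_q <- rlang::enquo(subgroup)
  if (!rlang::quo_is_null(sub_q)) {
    df <- dplyr::filter(df, !!sub_q)
  }
  if (nrow(df) < 2L) stop("fewer than 2 patients after filtering", call. = FALSE)
  df <- df[stats::complete.cases(df[[score]], df$time, df$event), ]

  cutpoint <- NA_real_
  if (method == "cutpoint") {
    cp <- find_cutpoint(df, score = score, minprop = minprop)
    cutpoint <- cp$cutpoint
    df$group <- ifelse(df[[score]] > cutpoint, "high", "low")
  } else {
    df$group <- median_split(df[[score]])
  }
  df$group <- factor(df$group, levels = c("low", "high"))

  km <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ km_curve(.x$time, .x$event)) |>
    dplyr::ungroup()

  lr <- logrank_test(df$time, df$event, df$group)
  cox <- cox_fit(time = df$time, event = df$event,
                 covariate = as.numeric(df$group == "high"))

  ev <- tapply(df$event, df$group, sum)
  reliable <- all(ev >= 2)
  if (!reliable) {
    warning("a group has fewer than 2 events; results flagged unreliable",
            call. = FALSE)
  }
  structure(
    list(data = df, method = method, cutpoint = cutpoint, km = km,
         logrank = lr, cox = cox,
         n = table(df$group), n_event = ev, reliable = reliable),
    class = "adi_survival"
  )
}

#' @export
print.adi_survival <- function(x, ...) {
  cat(sprintf("ADI survival stratification (%s%s)\n", x$method,
              if (!is.na(x$cutpoint)) sprintf(", cutpoint %.4g", x$cutpoint) else ""))
  cat(sprintf("  n: low %d / high %d; events: %d / %d\n",
              x$n[["low"]], x$n[["high"]],
              x$n_event[["low"]], x$n_event[["high"]]))
  cat(sprintf("  log-rank p = %.4g; HR = %.3f (95%% CI %.3f-%.3f)\n",
              x$logrank$p, x$cox$hr, x$cox$ci_low, x$cox$ci_high))
  if (!x$reliable) cat("  [unreliable: a group has < 2 events]\n")
  invisible(x)
}
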