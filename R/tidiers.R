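# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Cox fit
#'
#' @param x An `"adi_cox"` object from [cox_fit()].
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate` (log HR), `std.error`,
#'   `statistic` (Wald z), `p.value`, `hr`, `conf.low`, `conf.high`.
#' @method tidy adi_cox
#' @export
tidy.adi_cox <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(
    term = "score_high", estimate = x$beta, std.error = x$se,
    statistic = z, p.value = 2 * stats::pnorm(-abs(z)),
    hr = x$hr, conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @rdname tidy.adi_cox
#' @method glance adi_cox
#' @export
glance.adi_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 iterations = x$iterations, converged = x$converged,
                 ties = x$ties)
}

#' Tidy a log-rank test
#' @param x A `"logrank_test"` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' Tidy a cutpoint search
#' @param x An `"adi_cutpoint"` object.
#' @param ... Unused.
#' @return The candidate tibble (`threshold`, `statistic`, `n_low`,
#'   `n_high`); `glance()` gives the selected cutpoint.
#' @method tidy adi_cutpoint
#' @export
tidy.adi_cutpoint <- function(x, ...) x$candidates

#' @rdname tidy.adi_cutpoint
#' @method glance adi_cutpoint
#' @export
glance.adi_cutpoint <- function(x, ...) {
  tibble::tibble(cutpoint = x$cutpoint, statistic = x$statistic,
                 minprop = x$minprop, n_candidates = nrow(x$candidates))
}

#' Tidy a stratified survival analysis
#'
#' @param x An `"adi_survival"` object from [stratify_survival()].
#' @param ... Unused.
#' @return `tidy()`: per-group summary (`group`, `n`, `n_event`,
#'   `median_survival`). `glance()`: one row with the cutpoint, log-rank
#'   chi2/p and Cox HR with CI.
#' @method tidy adi_survival
#' @export
tidy.adi_survival <- function(x, ...) {
  x$data |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      n = dplyr::n(), n_event = sum(.data$event),
      median_survival = {
        km <- km_curve(.data$time, .data$event)
        idx <- which(km$survival <= 0.5)
        if (length(idx) > 0) km$time[idx[1]] else NA_real_
      },
      .groups = "drop"
    )
}

#' @rdname tidy.adi_survival
#' @method glance adi_survival
#' @export
glance.adi_survival <- function(x, ...) {
  tibble::tibble(
    method = x$method, cutpoint = x$cutpoint,
    n_low = as.integer(x$n[["low"]]), n_high = as.integer(x$n[["high"]]),
    logrank_chi2 = x$logrank$chi2, logrank_p = x$logrank$p,
    hr = x$cox$hr, hr_conf.low = x$cox$ci_low, hr_conf.high = x$cox$ci_high,
    cox_converged = x$cox$converged, reliable = x$reliable
  )
}
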