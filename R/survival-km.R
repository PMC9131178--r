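check_surv_input <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`
#' over the distinct event times, where `d_i` deaths occur among `n_i`
#' subjects at risk. Subjects censored exactly at an event time are counted
#' in the risk set at that time (the standard convention). `S` starts at 1,
#' is non-increasing, and is constant between event times.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators, 1 = death observed, 0 = censored.
#' @return A tibble of class `"km_curve"`, one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))$survival # 2/3, 1/3, 0
km_curve <- function(time, event) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  check_surv_input(time, event)
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), 0)
  n_event <- vapply(times, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(times, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble::tibble(time = times, n_risk = as.integer(n_risk),
                        n_event = as.integer(n_event),
                        n_censor = as.integer(n_censor), survival = surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time, the observed number of events in the first
#' group is compared with its expectation under the hypergeometric null
#' (events distributed over groups proportionally to their risk sets);
#' `chi2 = (sum(O - E))^2 / sum(V)` with the usual hypergeometric variance,
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param time,event Survival data as in [km_curve()].
#' @param group Two-level group labels (factor, character or logical).
#' @return Object of class `"logrank_test"`: list with `chi2`, `df`, `p`,
#'   `observed`, `expected` (per group), `n` (per group).
#' @export
logrank_test <- function(time, event, group) {
  if (is.data.frame(time)) {
    group <- event
    event <- time$event
    time <- time$time
  }
  check_surv_input(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  }
  group <- droplevels(group)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  g1 <- group == levels(group)[1]
  core <- logrank_core(time, event, g1)
  chi2 <- if (core$v > 0) core$o_minus_e^2 / core$v else 0
  d_total <- sum(event)
  o1 <- core$o1; e1 <- core$e1
  structure(
    list(chi2 = chi2, df = 1L,
         p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         observed = stats::setNames(c(o1, d_total - o1), levels(group)),
         expected = stats::setNames(c(e1, d_total - e1), levels(group)),
         n = stats::setNames(as.integer(table(group)), levels(group))),
    class = "logrank_test"
  )
}

# Vectorized two-group log-rank sums: O(n log n). `g1` is a logical vector
# marking the first group. Returns sum(O - E), sum(V) and the group-1
# observed/expected totals over the distinct event times.
logrank_core <- function(time, event, g1) {
  ord <- order(time)
  t <- time[ord]; e <- event[ord]; g <- g1[ord]
  ut <- unique(t)
  k <- match(t, ut)
  m <- length(ut)
  cnt <- tabulate(k, m)
  cnt1 <- tabulate(k[g], m)
  d <- tabulate(k[e == 1], m)
  d1 <- tabulate(k[e == 1 & g], m)
  n_at <- length(t) - c(0, cumsum(cnt))[seq_len(m)]
  n1_at <- sum(g) - c(0, cumsum(cnt1))[seq_len(m)]
  keep <- d > 0
  n <- n_at[keep]; n1 <- n1_at[keep]; dd <- d[keep]; dd1 <- d1[keep]
  ee <- dd * n1 / n
  vv <- ifelse(n > 1, dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1), 0)
  list(o_minus_e = sum(dd1 - ee), v = sum(vv), o1 = sum(dd1), e1 = sum(ee))
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}
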