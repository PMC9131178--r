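#' Maximally selected log-rank cutpoint
#'
#' Evaluates every candidate threshold placed at the midpoints between
#' consecutive distinct score values, keeping only thresholds at which both
#' resulting groups hold at least `minprop` of the cohort, and returns the
#' threshold maximizing the absolute standardized log-rank statistic
#' `|O - E| / sqrt(V)`. Ties in the statistic break toward the lower
#' threshold, deterministically. This is the maximally-selected-rank
#' approach used to dichotomize a continuous prognostic score.
#'
#' @param data Data frame with `time`, `event` and the score column.
#' @param score Score column name (default `"adi"`).
#' @param minprop Minimum fraction of subjects per group (default 0.1).
#' @return Object of class `"adi_cutpoint"`: `cutpoint`, `statistic` (the
#'   maximal standardized statistic), `minprop`, and `candidates` (tibble
#'   of all feasible thresholds with their statistics and group sizes).
#' @export
#' @examples
#' coh <- simulate_cohort(150, seed = 5)
#' find_cutpoint(coh)$cutpoint
find_cutpoint <- function(data, score = "adi", minprop = 0.1) {
  scores <- data[[score]]
  time <- data$time
  event <- data$event
  check_surv_input(time, event)
  if (minprop <= 0 || minprop >= 0.5) {
    stop("minprop must be in (0, 0.5)", call. = FALSE)
  }
  su <- sort(unique(scores))
  if (length(su) < 2L) stop("need >= 2 distinct scores", call. = FALSE)
  thresholds <- (su[-length(su)] + su[-1]) / 2
  n <- length(scores)
  n_min <- minprop * n
  rows <- purrr::map(thresholds, function(th) {
    high <- scores > th
    n_high <- sum(high)
    if (n_high < n_min || (n - n_high) < n_min) return(NULL)
    core <- logrank_core(time, event, high)
    stat <- if (core$v > 0) abs(core$o_minus_e) / sqrt(core$v) else 0
    tibble::tibble(threshold = th, statistic = stat,
                   n_low = n - n_high, n_high = n_high)
  })
  candidates <- dplyr::bind_rows(rows)
  if (nrow(candidates) == 0L) {
    stop("no feasible threshold at minprop = ", minprop, call. = FALSE)
  }
  best <- which.max(candidates$statistic)  # first max = lowest threshold
  structure(
    list(cutpoint = candidates$threshold[best],
         statistic = candidates$statistic[best],
         minprop = minprop, candidates = candidates),
    class = "adi_cutpoint"
  )
}

#' @export
print.adi_cutpoint <- function(x, ...) {
  cat(sprintf(
    "Maximally selected cutpoint: %.4g (standardized log-rank %.3f, minprop %.2f, %d candidates)\n",
    x$cutpoint, x$statistic, x$minprop, nrow(x$candidates)))
  invisible(x)
}

#' Median split of a score
#'
#' `high` iff score strictly exceeds the median; subjects at exactly the
#' median go to the low group. Output depends only on the values, not
#' their order.
#'
#' @param scores Numeric vector, >= 2 values, not all identical.
#' @return Character vector `"low"`/`"high"` per subject.
#' @export
#' @examples
#' median_split(c(0.1, 0.2, 0.3, 0.4))
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    stop("all scores identical; no split possible", call. = FALSE)
  }
  ifelse(scores > stats::median(scores), "high", "low")
}
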