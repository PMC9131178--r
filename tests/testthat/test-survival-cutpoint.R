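test_that("median split follows the documented strict-majority rule", {
  g <- median_split(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(g, c("low", "low", "high", "high"))
  # odd n: the subject at the median goes low
  g2 <- median_split(c(0.1, 0.2, 0.3))
  expect_equal(g2, c("low", "low", "high"))
  # permutation invariance of the assignment by value
  x <- c(0.5, 0.1, 0.9, 0.3)
  perm <- c(3, 1, 4, 2)
  expect_equal(median_split(x)[perm], median_split(x[perm]))
  expect_error(median_split(rep(0.3, 4)), "identical")
  expect_error(median_split(0.2), ">= 2")
})

test_that("cutpoint search separates a perfectly split toy cohort", {
  set.seed(1)
  df <- tibble::tibble(
    adi = rep(c(0.1, 0.9), each = 25),
    time = c(rexp(25, 1) + 0.01, rexp(25, 0.05) + 5),
    event = 1
  )
  cp <- find_cutpoint(df)
  expect_gt(cp$cutpoint, 0.1)
  expect_lt(cp$cutpoint, 0.9)
})

test_that("search equals brute force over all feasible thresholds", {
  set.seed(3)
  df <- tibble::tibble(
    adi = runif(30),
    time = rexp(30, 0.2) + 0.01,
    event = rbinom(30, 1, 0.8)
  )
  df$event[1] <- 1
  minprop <- 0.1
  cp <- find_cutpoint(df, minprop = minprop)
  # brute force: every midpoint, naive log-rank oracle
  su <- sort(unique(df$adi))
  mids <- (su[-length(su)] + su[-1]) / 2
  best_stat <- -Inf
  best_th <- NA
  for (th in mids) {
    hi <- df$adi > th
    if (sum(hi) < 3 || sum(!hi) < 3) next
    chi2 <- logrank_oracle(df$time, df$event, hi)
    stat <- sqrt(chi2)
    if (stat > best_stat + 1e-12) {
      best_stat <- stat
      best_th <- th
    }
  }
  expect_equal(cp$cutpoint, best_th, tolerance = 1e-12)
  expect_equal(cp$statistic, best_stat, tolerance = 1e-10)
  # minprop respected on every candidate
  expect_true(all(cp$candidates$n_low >= 3 & cp$candidates$n_high >= 3))
})

test_that("cutpoint recovers a strong planted step", {
  coh <- simulate_cohort(600, true_log_hr = log(3), true_cutpoint = 0.25,
                         censoring_rate = 0, seed = 17)
  cp <- find_cutpoint(coh)
  expect_lt(abs(cp$cutpoint - 0.25), 0.05)
})

test_that("infeasible requests are rejected", {
  df <- tibble::tibble(adi = rep(0.4, 10), time = 1:10, event = 1)
  expect_error(find_cutpoint(df), "distinct")
  df2 <- tibble::tibble(adi = c(0.1, rep(0.9, 9)), time = 1:10, event = 1)
  expect_error(find_cutpoint(df2, minprop = 0.4), "no feasible")
  expect_error(find_cutpoint(df2, minprop = 0.6), "minprop")
})
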