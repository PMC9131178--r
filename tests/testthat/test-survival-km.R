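test_that("product-limit estimates match hand computations", {
  # all censored: S identically 1
  km0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # three events: S = 2/3, 1/3, 0
  km1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # censoring shrinks the risk set: times {1, 2+, 3}
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km2$survival[km2$time == 3], 0, tolerance = 1e-12)
  expect_error(km_curve(c(0, 1), c(1, 1)), "positive")
})

test_that("KM agrees with the brute-force oracle over random small instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    time <- sample(1:6, n, replace = TRUE) # heavy ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1
    km <- km_curve(time, event)
    oracle <- km_oracle(time, event)
    got <- km$survival[match(oracle$time, km$time)]
    expect_equal(got, oracle$surv, tolerance = 1e-12)
    # invariants: non-increasing, within [0, 1]
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= -1e-12 & km$survival <= 1 + 1e-12))
  }
})

test_that("log-rank matches the per-time hypergeometric oracle exactly", {
  # fixed 6-subject toy with a tie
  time <- c(1, 1, 2, 3, 4, 5)
  event <- c(1, 1, 1, 0, 1, 1)
  grp <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$chi2, logrank_oracle(time, event, grp == "a"),
               tolerance = 1e-12)
  # random small instances
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    time <- sample(1:5, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    grp <- c("a", "b", sample(c("a", "b"), n - 2, replace = TRUE))
    if (sum(event) == 0) event[1] <- 1
    expect_equal(logrank_test(time, event, grp)$chi2,
                 logrank_oracle(time, event, grp == "a"), tolerance = 1e-12)
  }
})

test_that("log-rank is symmetric and null on duplicated groups", {
  time <- c(1, 2, 3, 4, 2, 5)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- rep(c("a", "b"), 3)
  lr_ab <- logrank_test(time, event, grp)
  lr_ba <- logrank_test(time, event, ifelse(grp == "a", "b", "a"))
  expect_equal(lr_ab$chi2, lr_ba$chi2, tolerance = 1e-12)
  # group b an exact copy of group a: chi2 = 0, p = 1
  dup <- logrank_test(rep(c(1, 2, 4), 2), rep(c(1, 1, 0), 2),
                      rep(c("a", "b"), each = 3))
  expect_equal(dup$chi2, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1)
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two")
})
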