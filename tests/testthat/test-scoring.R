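make_preds <- function(labels, slide_id = "s1") {
  tibble::tibble(slide_id = slide_id, label = labels)
}

test_that("slide composition counts exactly and rejects mixed slides", {
  comp <- slide_composition(make_preds(rep("TUM", 100)))
  expect_equal(comp$n[comp$label == "TUM"], 100L)
  expect_equal(sum(comp$n), 100L)
  empty <- slide_composition(make_preds(character(0)))
  expect_true(all(empty$n == 0L))
  expect_error(
    slide_composition(dplyr::bind_rows(make_preds("TUM", "a"),
                                       make_preds("ADI", "b"))),
    "mix slide_ids")
})

test_that("the ADI score is the adipose fraction of classified tiles", {
  labels <- c(rep("ADI", 200), rep("TUM", 500), rep("STR", 200),
              rep("LYM", 100))
  comp <- slide_composition(make_preds(labels))
  expect_identical(adi_score(comp), 0.2)
  expect_identical(adi_score(slide_composition(make_preds(rep("TUM", 50)))), 0)
  expect_identical(adi_score(slide_composition(make_preds(rep("ADI", 7)))), 1)
  # zero classified tiles: missing, never 0
  expect_true(is.na(adi_score(slide_composition(make_preds(character(0))))))
  # denominator option: model-labeled BACK excluded on request
  comp2 <- slide_composition(make_preds(c(rep("ADI", 20), rep("BACK", 30),
                                          rep("TUM", 50))))
  expect_equal(adi_score(comp2), 0.2)
  expect_equal(adi_score(comp2, drop_back = TRUE), 20 / 70)
})

test_that("patient aggregation pools counts, not proportions", {
  c1 <- slide_composition(make_preds(rep("ADI", 100), "sl_a"))
  c2 <- slide_composition(make_preds(rep("TUM", 100), "sl_b"))
  mapping <- tibble::tibble(slide_id = c("sl_a", "sl_b"),
                            patient_id = "p1")
  ps <- aggregate_patient_scores(dplyr::bind_rows(c1, c2), mapping)
  expect_equal(ps$adi, 0.5)
  expect_equal(ps$n_tiles, 200L)
  expect_equal(rowSums(as.matrix(ps[, paste0("prop_", tissue_classes())])), 1,
               ignore_attr = TRUE)
  # order invariance
  ps_rev <- aggregate_patient_scores(dplyr::bind_rows(c2, c1), mapping)
  expect_equal(ps, ps_rev)
  # pooling equals scoring the concatenated stream
  concat <- slide_composition(make_preds(c(rep("ADI", 100), rep("TUM", 100)),
                                         "sl_a"))
  expect_equal(adi_score(concat), ps$adi)
  # single slide: identical to the slide-level score
  one <- aggregate_patient_scores(c1)
  expect_equal(one$adi, adi_score(c1))
})

test_that("spearman correlation matches the rank formula and handles edge cases", {
  x <- c(0.12, 0.31, 0.05, 0.44, 0.27, 0.18, 0.39, 0.08, 0.22, 0.35)
  y <- c(21.3, 27.8, 19.4, 30.2, 24.9, 23.1, 28.8, 20.6, 24.0, 26.5)
  df <- tibble::tibble(adi = x, bmi = y)
  res <- correlate_scores(df)
  rho_direct <- 1 - 6 * sum((rank(x) - rank(y))^2) / (10 * (10^2 - 1))
  expect_equal(res$rho, rho_direct, tolerance = 1e-12)
  expect_equal(correlate_scores(tibble::tibble(adi = x, bmi = x))$rho, 1)
  expect_equal(correlate_scores(tibble::tibble(adi = x, bmi = -x))$rho, -1)
  # missing pairs dropped; constant input -> missing rho
  df$bmi[3] <- NA
  expect_equal(correlate_scores(df)$n, 9L)
  const <- tibble::tibble(adi = rep(0.2, 5), bmi = 1:5)
  expect_true(is.na(correlate_scores(const)$rho))
  expect_error(correlate_scores(df[1:2, ]), ">= 3")
})
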