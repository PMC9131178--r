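test_that("tile features hit their closed-form anchors", {
  white <- array(255, c(224, 224, 3))
  fw <- extract_tile_features(white)
  expect_equal(unname(fw["white_frac"]), 1)
  expect_equal(unname(fw["dark_blobs"]), 0)
  expect_equal(unname(fw["edge_density"]), 0)
  black <- array(0, c(224, 224, 3))
  fb <- extract_tile_features(black)
  expect_equal(unname(fb["white_frac"]), 0)
  expect_equal(unname(fb["dark_blobs"]), 1) # one giant connected component
  expect_error(extract_tile_features(matrix(0, 4, 4)), "H x W x 3")
})

test_that("lymphocyte tiles show far more dark blobs than adipose tiles", {
  for (seed in c(2, 4)) {
    f_lym <- extract_tile_features(simulate_tile("LYM", seed = seed))
    f_adi <- extract_tile_features(simulate_tile("ADI", seed = seed))
    expect_gt(f_lym[["dark_blobs"]], f_adi[["dark_blobs"]] + 20)
  }
})

test_that("label assignment is argmax with lowest-index tie-break", {
  uniform <- matrix(1 / 9, nrow = 1, ncol = 9)
  expect_equal(label_from_probs(uniform), "ADI")
  p <- matrix(0, 2, 9)
  p[1, 9] <- 1                     # all mass on TUM
  p[2, c(2, 5)] <- 0.5             # tie BACK/MUC -> BACK (lower index)
  expect_equal(label_from_probs(p), c("TUM", "BACK"))
  expect_error(label_from_probs(matrix(0.5, 1, 9)), "sum to 1")
  expect_equal(label_from_probs(matrix(numeric(0), 0, 9)), character(0))
})

test_that("reference classifier is deterministic, accurate, and validates input", {
  feats <- simulate_tile_features(25, seed = 101)
  m1 <- fit_tissue_classifier(feats, seed = 11)
  m2 <- fit_tissue_classifier(feats, seed = 11)
  expect_identical(coef(m1$fit), coef(m2$fit))
  expect_identical(m1$holdout_accuracy, m2$holdout_accuracy)
  expect_gte(m1$holdout_accuracy, 0.9)
  expect_error(fit_tissue_classifier(feats[feats$label != "MUC", ],
                                     seed = 1), "missing training tiles")
  expect_error(fit_tissue_classifier(feats[1:40, ], seed = 1), "missing")
})

test_that("predictions preserve order, sum to one, and recover mosaic truth", {
  model <- test_classifier()
  sl <- simulate_slide(5, 5, c(ADI = 0.2, TUM = 0.8), seed = 21)
  tiles <- tile_slide(sl$slide)
  preds <- classify_tiles(tiles, model)
  expect_equal(nrow(preds), nrow(tiles))
  expect_equal(preds$row, tiles$row)
  probs <- as.matrix(preds[, paste0("p_", tissue_classes())])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(probs >= 0))
  truth <- sl$labels[cbind(preds$row + 1, preds$col + 1)]
  expect_gte(mean(preds$label == truth), 0.9)
  # empty stream
  empty <- classify_tiles(tiles[0, ], model)
  expect_equal(nrow(empty), 0)
  expect_true(all(paste0("p_", tissue_classes()) %in% names(empty)))
})

test_that("classifiers survive JSON serialization with identical predictions", {
  model <- test_classifier()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.json")
  save_classifier(model, p)
  loaded <- load_classifier(p)
  tiles <- tile_slide(simulate_slide(2, 2, c(LYM = 1), seed = 3)$slide)
  p1 <- classify_tiles(tiles, model)
  p2 <- classify_tiles(tiles, loaded)
  expect_equal(p1$label, p2$label)
  expect_equal(as.matrix(p1[, -(1:4)]), as.matrix(p2[, -(1:4)]),
               tolerance = 1e-10)
})
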