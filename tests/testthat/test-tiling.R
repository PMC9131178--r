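test_that("tile grids follow the rescale-then-floor arithmetic", {
  sl <- slide_image(array(255, c(2240, 2240, 3)), mpp = 0.5)
  expect_equal(nrow(make_tile_grid(sl)), 100)
  sl2 <- slide_image(array(255, c(2240, 2240, 3)), mpp = 0.25)
  expect_equal(nrow(make_tile_grid(sl2)), 25)
  sl3 <- slide_image(array(255, c(500, 300, 3)), mpp = 0.5)
  g3 <- make_tile_grid(sl3)
  expect_equal(nrow(g3), 2)
  expect_true(all(g3$y0 + 224 <= 500 & g3$x0 + 224 <= 300))
  # smaller than one tile: empty grid with a warning, not an error
  tiny <- slide_image(array(255, c(100, 100, 3)), mpp = 0.5)
  expect_warning(g <- make_tile_grid(tiny), "smaller than one tile")
  expect_equal(nrow(g), 0)
})

test_that("background rule: strict gray > 200 after global average pooling", {
  expect_true(is_background(array(255, c(8, 8, 3))))
  expect_false(is_background(array(0, c(8, 8, 3))))
  # channel means (210, 200, 190) pool to exactly 200: kept
  tile <- array(0, c(8, 8, 3))
  tile[, , 1] <- 210; tile[, , 2] <- 200; tile[, , 3] <- 190
  expect_equal(tile_gray_value(tile), 200)
  expect_false(is_background(tile))
  expect_true(is_background(tile, threshold = 199.9))
})

test_that("normalization is the stated affine map and inverts exactly", {
  tile <- simulate_tile("STR", seed = 2)
  ident <- normalization_stats(c(0, 0, 0), c(1, 1, 1))
  expect_equal(normalize_tile(tile, ident), tile / 255, tolerance = 1e-12)
  stats <- normalization_stats(c(0.5, 0.4, 0.45), c(0.2, 0.25, 0.3))
  const <- array(0, c(4, 4, 3))
  for (k in 1:3) const[, , k] <- stats$mean[k] * 255
  expect_true(all(abs(normalize_tile(const, stats)) < 1e-12))
  round_trip <- denormalize_tile(normalize_tile(tile, stats), stats)
  expect_lt(max(abs(round_trip - tile)), 1e-6)
  expect_error(normalization_stats(c(0, 0, 0), c(1, 0, 1)), "std")
})

test_that("tile_slide keeps only foreground and conserves counts", {
  sl <- simulate_slide(6, 6, c(TUM = 0.7, LYM = 0.3), background_margin = 1,
                       seed = 5)
  # 6x6 grid with a 1-tile BACK margin: 20 background, 16 interior
  tiles <- tile_slide(sl$slide)
  rep <- tiling_report(tiles)
  expect_equal(rep$total, 36)
  expect_equal(rep$kept + rep$removed, rep$total)
  expect_gte(rep$removed, 20)
  expect_equal(nrow(tiles), rep$kept)
  expect_true(all(tiles$gray <= 200))

  all_bg <- simulate_slide(2, 2, c(BACK = 1), seed = 1)
  rep_bg <- tiling_report(tile_slide(all_bg$slide))
  expect_equal(rep_bg$kept, 0)

  no_bg <- simulate_slide(2, 2, c(TUM = 1), seed = 1)
  rep_fg <- tiling_report(tile_slide(no_bg$slide))
  expect_equal(rep_fg$kept, rep_fg$total)

  # determinism: identical tile sets and ordering
  t1 <- tile_slide(sl$slide)
  expect_identical(tiles$pixels, t1$pixels)
  expect_identical(tiles[, c("row", "col", "gray")],
                   t1[, c("row", "col", "gray")])
})

test_that("brightening every pixel never turns background into foreground", {
  sl <- simulate_slide(3, 3, c(DEB = 0.5, MUC = 0.5), seed = 6, tile_px = 32)
  px <- sl$slide$pixels
  bright <- slide_image(pmin(px + 30, 255), mpp = 0.5, "b")
  base_rep <- tiling_report(tile_slide(sl$slide, tile_px = 32))
  bright_rep <- tiling_report(tile_slide(bright, tile_px = 32))
  expect_gte(bright_rep$removed, base_rep$removed)
})

test_that("rescaling halves the grid of a double-resolution mosaic", {
  sl <- simulate_slide(4, 4, c(TUM = 1), seed = 7, tile_px = 112,
                       mpp = 1.0)
  # 448 px at 1.0 mpp -> 896 px at 0.5 mpp -> 4x4 tiles of 224
  g <- make_tile_grid(sl$slide)
  expect_equal(nrow(g), 16)
  tiles <- tile_slide(sl$slide)
  expect_equal(nrow(tiles), 16)
})
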