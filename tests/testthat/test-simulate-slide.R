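test_that("largest-remainder apportionment gives exact, testable counts", {
  counts <- apportion_tiles(c(ADI = 0.2, TUM = 0.8), 100)
  expect_identical(counts, c(ADI = 20L, TUM = 80L))
  # remainder cases against a direct largest-remainder computation
  comp <- c(ADI = 0.33, TUM = 0.67)
  counts <- apportion_tiles(comp, 400)
  expect_identical(sum(counts), 400L)
  expect_lte(abs(counts[["ADI"]] / 400 - 0.33), 1 / 400)
  # property: counts always sum to n, each within 1 of its quota
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(4)
    p <- p / sum(p)
    names(p) <- c("ADI", "LYM", "STR", "TUM")
    n <- sample(1:500, 1)
    cnt <- apportion_tiles(p, n)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(abs(cnt - p * n) < 1))
  }
  expect_error(apportion_tiles(c(ADI = 0.5, TUM = 0.6), 10), "sum to 1")
  expect_error(apportion_tiles(c(ADI = -0.1, TUM = 1.1), 10), ">= 0")
})

test_that("mosaic slides realize their composition and ground truth exactly", {
  sl <- simulate_slide(10, 10, c(ADI = 0.2, TUM = 0.8), seed = 1, tile_px = 16)
  expect_equal(sum(sl$labels == "ADI"), 20)
  expect_equal(sum(sl$labels == "TUM"), 80)
  expect_equal(dim(sl$slide$pixels), c(160, 160, 3))

  single <- simulate_slide(1, 1, c(BACK = 1), seed = 1, tile_px = 16)
  expect_equal(single$labels[1, 1], "BACK")

  sl2 <- simulate_slide(20, 20, c(ADI = 0.33, TUM = 0.67), seed = 2,
                        tile_px = 8)
  expect_lte(abs(mean(sl2$labels == "ADI") - 0.33), 1 / 400)

  # background margin surrounds the interior
  slm <- simulate_slide(6, 6, c(TUM = 1), background_margin = 1, seed = 3,
                        tile_px = 8)
  expect_true(all(slm$labels[1, ] == "BACK"))
  expect_true(all(slm$labels[, 6] == "BACK"))
  expect_true(all(slm$labels[2:5, 2:5] == "TUM"))

  expect_identical(simulate_slide(3, 3, c(ADI = 1), seed = 9, tile_px = 8),
                   simulate_slide(3, 3, c(ADI = 1), seed = 9, tile_px = 8))
})

test_that("slides round-trip through PNG plus sidecar JSON", {
  dir <- withr::local_tempdir()
  sl <- simulate_slide(2, 3, c(LYM = 0.5, MUS = 0.5), seed = 4, tile_px = 8,
                       mpp = 0.25, slide_id = "rt1")
  write_slide(sl, file.path(dir, "rt1"))
  back <- read_slide(file.path(dir, "rt1"))
  expect_equal(back$mpp, 0.25)
  expect_equal(back$slide_id, "rt1")
  expect_equal(attr(back, "labels"), sl$labels)
  # PNG stores 8-bit: pixels agree to rounding
  expect_lt(max(abs(back$pixels - sl$slide$pixels)), 0.51)
})
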