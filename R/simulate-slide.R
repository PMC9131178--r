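#' Apportion tile counts to classes by largest remainder
#'
#' Converts target class fractions into integer tile counts that sum
#' exactly to `n_tiles`: each class first receives `floor(fraction * n)`
#' tiles, then the remaining tiles go one-by-one to the classes with the
#' largest fractional remainders (ties broken by class order). This makes
#' realized compositions exactly predictable: the realized fraction never
#' deviates from the target by more than `1 / n_tiles`.
#'
#' @param composition Named numeric vector of class fractions, non-negative,
#'   summing to 1 within 1e-9. Names must be valid tissue classes.
#' @param n_tiles Total number of tiles to apportion.
#' @return Named integer vector of counts summing to `n_tiles`.
#' @export
apportion_tiles <- function(composition, n_tiles) {
  if (is.null(names(composition)) || !all(names(composition) %in% tissue_classes())) {
    stop("composition must be named with valid tissue classes", call. = FALSE)
  }
  if (any(composition < 0)) stop("composition fractions must be >= 0", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  quota <- composition * n_tiles
  counts <- floor(quota)
  leftover <- n_tiles - sum(counts)
  if (leftover > 0) {
    rem <- quota - counts
    take <- order(-rem, seq_along(rem))[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(composition))
}

#' Generate a synthetic mosaic slide with known class composition
#'
#' Builds a slide as a `grid_rows x grid_cols` mosaic of synthetic tissue
#' tiles. Per-class tile counts follow [apportion_tiles()] applied to
#' `composition` over the interior tiles; classes are then placed at random
#' grid positions. An optional border of pure-background tiles
#' (`background_margin`) emulates the empty glass around a tissue section.
#' The ground-truth label grid is returned alongside the pixels, so every
#' downstream stage (tiling, classification, scoring) can be tested against
#' known truth.
#'
#' @param grid_rows,grid_cols Tile counts of the mosaic.
#' @param composition Named fractions over tissue classes for the interior
#'   (non-margin) tiles; non-negative, summing to 1.
#' @param mpp Declared microns per pixel of the slide (default 0.5).
#' @param background_margin Number of pure-BACK border tile rings (default 0).
#' @param tile_px Tile side length in pixels (default 224).
#' @param seed Integer seed; the whole slide is reproducible from it.
#' @param slide_id Identifier stored with the slide.
#' @return A list of class `"synthetic_slide"` with elements `slide` (a
#'   [slide_image()]), `labels` (character `grid_rows x grid_cols` matrix of
#'   ground-truth classes), `composition` (realized interior class counts)
#'   and `seed`.
#' @export
#' @examples
#' sl <- simulate_slide(4, 4, c(ADI = 0.25, TUM = 0.75), seed = 1, tile_px = 32)
#' table(sl$labels)
simulate_slide <- function(grid_rows, grid_cols, composition,
                           mpp = 0.5, background_margin = 0,
                           tile_px = 224L, seed = 1L,
                           slide_id = "synthetic") {
  if (grid_rows < 1 || grid_cols < 1) stop("grid must have >= 1 tile", call. = FALSE)
  interior_rows <- grid_rows - 2 * background_margin
  interior_cols <- grid_cols - 2 * background_margin
  if (background_margin > 0 && (interior_rows < 1 || interior_cols < 1)) {
    stop("background margin leaves no interior tiles", call. = FALSE)
  }
  n_interior <- interior_rows * interior_cols
  counts <- apportion_tiles(composition, n_interior)

  labels <- matrix("BACK", nrow = grid_rows, ncol = grid_cols)
  interior_lab <- rep(names(counts), times = counts)
  interior_lab <- with_local_seed(seed, sample(interior_lab))
  ridx <- background_margin + seq_len(interior_rows)
  cidx <- background_margin + seq_len(interior_cols)
  labels[ridx, cidx] <- matrix(interior_lab, interior_rows, interior_cols)

  px <- as.integer(tile_px)
  pixels <- array(0, dim = c(grid_rows * px, grid_cols * px, 3))
  for (i in seq_len(grid_rows)) {
    for (j in seq_len(grid_cols)) {
      tseed <- derive_seed(seed, (i - 1) * grid_cols + j)
      tile <- simulate_tile(labels[i, j], seed = tseed, tile_px = px)
      pixels[(i - 1) * px + seq_len(px), (j - 1) * px + seq_len(px), ] <- tile
    }
  }
  structure(
    list(
      slide = slide_image(pixels, mpp = mpp, slide_id = slide_id),
      labels = labels,
      composition = counts,
      seed = as.integer(seed)
    ),
    class = "synthetic_slide"
  )
}
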