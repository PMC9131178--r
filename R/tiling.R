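#' Construct a slide image
#'
#' Lightweight container for a raster slide: an `H x W x 3` 8-bit pixel
#' array plus the physical resolution it was scanned at, declared as
#' microns per pixel (mpp). The mpp is what links pixel geometry to tissue
#' geometry and drives rescaling to the working resolution.
#'
#' @param pixels Numeric `H x W x 3` array, values in 0..255.
#' @param mpp Microns per pixel, > 0.
#' @param slide_id Identifier string.
#' @return An object of class `"slide_image"`.
#' @export
slide_image <- function(pixels, mpp, slide_id = "slide") {
  assert_rgb_tile(pixels, "slide")
  if (!is.numeric(mpp) || length(mpp) != 1L || mpp <= 0) {
    stop("mpp must be a single positive number", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1)) stop("slide must be at least 1 x 1", call. = FALSE)
  structure(list(pixels = pixels, mpp = mpp, slide_id = as.character(slide_id)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image '%s': %d x %d px @ %.3g mpp>\n",
              x$slide_id, d[1], d[2], x$mpp))
  invisible(x)
}

# Bilinear rescale of an H x W x 3 array to new_h x new_w.
rescale_bilinear <- function(pixels, new_h, new_w) {
  d <- dim(pixels)
  if (new_h == d[1] && new_w == d[2]) return(pixels)
  out <- EBImage::resize(pixels, w = new_h, h = new_w, filter = "bilinear")
  clamp255(array(out, dim = c(new_h, new_w, 3)))
}

#' Lay out a non-overlapping tile grid over a slide
#'
#' The slide is conceptually rescaled by `slide$mpp / target_mpp` (bilinear)
#' to the working resolution, then covered by non-overlapping `tile_px`
#' squares in 0-based row-major order. Partial tiles at the right/bottom
#' edges are dropped, never padded. If the rescaled image is smaller than
#' one tile in either dimension, an empty grid is returned with a warning.
#'
#' @param slide A [slide_image()].
#' @param tile_px Tile side length in pixels at the working resolution
#'   (default 224).
#' @param target_mpp Working resolution in microns per pixel (default 0.5).
#' @return A tibble with columns `row`, `col` (0-based grid indices) and
#'   `y0`, `x0` (0-based pixel origins in the rescaled frame), with
#'   attributes `tile_px`, `scale_factor`, `rescaled_dim`.
#' @export
#' @examples
#' sl <- slide_image(array(255, c(448, 448, 3)), mpp = 0.5)
#' nrow(make_tile_grid(sl)) # 2 x 2 = 4 tiles
make_tile_grid <- function(slide, tile_px = 224L, target_mpp = 0.5) {
  stopifnot(inherits(slide, "slide_image"))
  if (target_mpp <= 0) stop("target_mpp must be > 0", call. = FALSE)
  scale <- slide$mpp / target_mpp
  d <- dim(slide$pixels)
  new_h <- floor(d[1] * scale)
  new_w <- floor(d[2] * scale)
  n_rows <- new_h %/% tile_px
  n_cols <- new_w %/% tile_px
  if (n_rows < 1 || n_cols < 1) {
    warning("rescaled slide smaller than one tile; empty grid", call. = FALSE)
    n_rows <- 0L
    n_cols <- 0L
  }
  grid <- tidyr::expand_grid(row = seq_len(n_rows) - 1L,
                             col = seq_len(n_cols) - 1L)
  grid <- dplyr::mutate(grid,
                        y0 = .data$row * as.integer(tile_px),
                        x0 = .data$col * as.integer(tile_px))
  attr(grid, "tile_px") <- as.integer(tile_px)
  attr(grid, "scale_factor") <- scale
  attr(grid, "rescaled_dim") <- c(new_h, new_w)
  grid
}

#' Gray value of a tile by global average pooling
#'
#' Pools the 224x224 tile into a single pixel by global averaging, then
#' averages the three pooled channel values (unweighted) to one gray value.
#'
#' @param pixels An `H x W x 3` pixel array in 0..255.
#' @return Single gray value in `[0, 255]`.
#' @export
tile_gray_value <- function(pixels) {
  assert_rgb_tile(pixels)
  mean(c(mean(pixels[, , 1]), mean(pixels[, , 2]), mean(pixels[, , 3])))
}

#' Background test for a tile
#'
#' A tile is background iff its global-average gray value strictly exceeds
#' `threshold` (default 200): pale, mostly-glass tiles pool to a bright
#' gray, tissue tiles do not. The inequality is strict, so a tile with
#' gray value exactly 200 is kept.
#'
#' @param pixels An `H x W x 3` pixel array in 0..255.
#' @param threshold Gray cutoff (default 200).
#' @return Logical flag.
#' @export
#' @examples
#' is_background(array(255, c(4, 4, 3))) # TRUE
#' is_background(array(0, c(4, 4, 3)))   # FALSE
is_background <- function(pixels, threshold = 200) {
  tile_gray_value(pixels) > threshold
}

#' Per-channel normalization statistics
#'
#' @param mean,sd Length-3 numeric vectors of per-channel means and
#'   standard deviations on the 0..1 scale.
#' @return A list of class `"normalization_stats"`.
#' @export
normalization_stats <- function(mean, sd) {
  stopifnot(length(mean) == 3L, length(sd) == 3L)
  if (any(sd <= 0)) stop("normalization std must be > 0 per channel", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "normalization_stats")
}

default_stats_cache <- new.env(parent = emptyenv())

#' Default normalization statistics from synthetic training tiles
#'
#' Channel means and standard deviations computed (once per session, then
#' cached) from a fixed-seed batch of synthetic tiles, five per foreground
#' class. External statistics (e.g. ImageNet-style) can be supplied to
#' [normalize_tile()] instead.
#'
#' @return A [normalization_stats()] object.
#' @export
default_normalization_stats <- function() {
  if (is.null(default_stats_cache$stats)) {
    classes <- setdiff(tissue_classes(), "BACK")
    sums <- matrix(0, nrow = 2, ncol = 3)
    n_px <- 0
    for (i in seq_along(classes)) {
      for (r in 1:5) {
        tile <- simulate_tile(classes[i], seed = derive_seed(20240501, i * 10 + r)) / 255
        for (k in 1:3) {
          sums[1, k] <- sums[1, k] + sum(tile[, , k])
          sums[2, k] <- sums[2, k] + sum(tile[, , k]^2)
        }
        n_px <- n_px + length(tile[, , 1])
      }
    }
    mu <- sums[1, ] / n_px
    sdv <- sqrt(sums[2, ] / n_px - mu^2)
    default_stats_cache$stats <- normalization_stats(mu, sdv)
  }
  default_stats_cache$stats
}

#' Normalize a tile to the training color distribution
#'
#' Per channel: `(pixel / 255 - mean) / sd`. Returns a floating-point tile;
#' the input is unchanged.
#'
#' @param pixels An `H x W x 3` pixel array in 0..255.
#' @param stats A [normalization_stats()] object (default: statistics of
#'   the synthetic training tiles).
#' @return Floating-point array of the same shape.
#' @export
normalize_tile <- function(pixels, stats = default_normalization_stats()) {
  assert_rgb_tile(pixels)
  stopifnot(inherits(stats, "normalization_stats"))
  out <- pixels / 255
  for (k in 1:3) out[, , k] <- (out[, , k] - stats$mean[k]) / stats$sd[k]
  out
}

#' Invert [normalize_tile()]
#' @param pixels Normalized floating-point tile.
#' @param stats The statistics used to normalize.
#' @return Pixel array back on the 0..255 scale.
#' @export
denormalize_tile <- function(pixels, stats = default_normalization_stats()) {
  out <- pixels
  for (k in 1:3) out[, , k] <- out[, , k] * stats$sd[k] + stats$mean[k]
  out * 255
}

#' Cut a slide into kept (non-background) tiles
#'
#' Rescales the slide to the working resolution, lays out the
#' non-overlapping grid of [make_tile_grid()], computes each tile's
#' global-average gray value, and drops tiles whose gray value strictly
#' exceeds `background_threshold`. The kept tiles are returned as a tibble
#' in row-major order with their pixel arrays in a list-column; the tiling
#' report (total / removed / kept, with kept + removed = total) is attached
#' as the `"report"` attribute and retrievable via [tiling_report()].
#'
#' @param slide A [slide_image()].
#' @param tile_px,target_mpp Grid parameters, see [make_tile_grid()].
#' @param background_threshold Gray cutoff for background removal
#'   (default 200).
#' @param normalize If TRUE, add a `pixels_norm` list-column of
#'   color-normalized tiles (default FALSE: the reference classifier works
#'   on raw 8-bit tiles, CNN-style models consume normalized ones).
#' @param stats Normalization statistics when `normalize = TRUE`.
#' @return Tibble of kept tiles: `slide_id`, `row`, `col`, `gray`,
#'   `pixels` (list of 224x224x3 arrays), optionally `pixels_norm`.
#' @export
tile_slide <- function(slide, tile_px = 224L, target_mpp = 0.5,
                       background_threshold = 200, normalize = FALSE,
                       stats = NULL) {
  stopifnot(inherits(slide, "slide_image"))
  grid <- make_tile_grid(slide, tile_px = tile_px, target_mpp = target_mpp)
  px <- attr(grid, "tile_px")
  rd <- attr(grid, "rescaled_dim")
  rescaled <- rescale_bilinear(slide$pixels, rd[1], rd[2])

  tiles <- purrr::pmap(grid, function(row, col, y0, x0) {
    rescaled[y0 + seq_len(px), x0 + seq_len(px), , drop = FALSE]
  })
  gray <- purrr::map_dbl(tiles, tile_gray_value)
  bg <- gray > background_threshold
  out <- tibble::tibble(
    slide_id = slide$slide_id,
    row = grid$row, col = grid$col,
    gray = gray,
    pixels = tiles
  )[!bg, , drop = FALSE]
  if (normalize) {
    if (is.null(stats)) stats <- default_normalization_stats()
    out$pixels_norm <- purrr::map(out$pixels, normalize_tile, stats = stats)
  }
  report <- tibble::tibble(
    slide_id = slide$slide_id,
    total = nrow(grid),
    removed = sum(bg),
    kept = sum(!bg)
  )
  attr(out, "report") <- report
  out
}

#' Retrieve the tiling report attached by [tile_slide()]
#' @param tiles Result of [tile_slide()].
#' @return Tibble with columns `slide_id`, `total`, `removed`, `kept`.
#' @export
tiling_report <- function(tiles) {
  rep <- attr(tiles, "report")
  if (is.null(rep)) stop("no tiling report attached", call. = FALSE)
  rep
}
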