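#' Extract summary features from a tile
#'
#' A fixed-length, deterministic feature vector summarizing the color and
#' texture of a 224x224 RGB tile, serving as input to the desk-scale
#' reference classifier:
#'
#' * per-channel means and standard deviations (6),
#' * `white_frac`: fraction of pixels with all channels > 230 (fat
#'   vacuoles, glass),
#' * `dark_blobs`: count of connected components of pixels with all
#'   channels < 120 and area >= 10 px (nuclei, lymphocytes),
#' * `edge_density`: mean gradient magnitude of the gray image,
#' * `orientation`: horizontal share of gradient energy,
#'   `mean|dx| / (mean|dx| + mean|dy|)` (separates oriented fiber
#'   textures),
#' * `glcm_contrast`: gray-level co-occurrence contrast at offset (0, 1)
#'   over 16 gray levels (granularity).
#'
#' @param pixels A 224x224x3 (or any `H x W x 3`) array in 0..255, or a
#'   tibble of tiles from [tile_slide()] with a `pixels` list-column.
#' @return Named numeric vector of 11 features, or (for a tibble input) the
#'   tibble with the pixel column replaced by feature columns.
#' @export
#' @examples
#' extract_tile_features(simulate_tile("LYM", seed = 1))["dark_blobs"]
extract_tile_features <- function(pixels) {
  if (is.data.frame(pixels)) {
    feats <- purrr::map(pixels$pixels, extract_tile_features)
    out <- dplyr::bind_cols(
      dplyr::select(pixels, -dplyr::any_of(c("pixels", "pixels_norm"))),
      tibble::as_tibble(do.call(rbind, feats))
    )
    return(out)
  }
  assert_rgb_tile(pixels)
  r <- pixels[, , 1]; g <- pixels[, , 2]; b <- pixels[, , 3]
  gray <- (r + g + b) / 3

  white <- r > 230 & g > 230 & b > 230
  dark <- r < 120 & g < 120 & b < 120
  dark_blobs <- 0
  if (any(dark)) {
    lab <- EBImage::bwlabel(dark)
    sizes <- tabulate(lab[lab > 0])
    dark_blobs <- sum(sizes >= 10)
  }

  dx <- abs(gray[, -1] - gray[, -ncol(gray)])
  dy <- abs(gray[-1, ] - gray[-nrow(gray), ])
  mdx <- mean(dx); mdy <- mean(dy)
  edge_density <- (mdx + mdy) / 2
  orientation <- if (mdx + mdy > 0) mdx / (mdx + mdy) else 0.5

  q <- pmin(floor(gray / 16), 15)
  a <- q[, -ncol(q)]; bq <- q[, -1]
  glcm_contrast <- mean((a - bq)^2)

  c(r_mean = mean(r), g_mean = mean(g), b_mean = mean(b),
    r_sd = stats::sd(r), g_sd = stats::sd(g), b_sd = stats::sd(b),
    white_frac = mean(white), dark_blobs = dark_blobs,
    edge_density = edge_density, orientation = orientation,
    glcm_contrast = glcm_contrast)
}

#' Generate a labeled synthetic feature table
#'
#' Streams `n_per_class` synthetic tiles per tissue class through
#' [extract_tile_features()], keeping only the feature rows (constant
#' memory). This is the training material for the reference classifier.
#'
#' @param n_per_class Tiles per class.
#' @param seed Integer seed; tile sub-seeds are derived deterministically.
#' @param classes Classes to generate (default all nine).
#' @return Tibble with `label` plus the 11 feature columns.
#' @export
simulate_tile_features <- function(n_per_class, seed = 1L,
                                   classes = tissue_classes()) {
  rows <- vector("list", length(classes) * n_per_class)
  idx <- 1L
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      tile <- simulate_tile(classes[ci],
                            seed = derive_seed(seed, ci * 100000L + r))
      rows[[idx]] <- c(extract_tile_features(tile))
      idx <- idx + 1L
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$label <- rep(classes, each = n_per_class)
  dplyr::relocate(out, "label")
}
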