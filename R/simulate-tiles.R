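#' Default texture parameters for the nine synthetic tissue classes
#'
#' Each synthetic class is a parametric texture built from simple primitives
#' (discs, ellipses, rings, oriented stripes, speckle noise) on a stained
#' base color, chosen so that the classes are visually separable and carry
#' the hallmark appearance of their real counterparts: adipose as large
#' white vacuoles with thin pink rims, background as near-uniform white,
#' lymphocyte aggregates as dense small dark-blue nuclei, tumor epithelium
#' as crowded dark-purple ellipses, stroma and muscle as oriented pink
#' fibers at different orientations, normal mucosa as ring-shaped gland
#' outlines, mucus as a pale blue wash, debris as granular pink-gray
#' speckle. Realism is not the goal; class separability for a desk-scale
#' classifier is.
#'
#' All foreground classes have a mean gray value safely below the
#' background-removal threshold of 200, and BACK sits safely above it, so
#' the background filter behaves on synthetic slides as it does on real
#' H&E tiles.
#'
#' @param class One of [tissue_classes()].
#' @return A list with fields `class`, `base` (RGB base color),
#'   `element_color`, `accent`, `element_density` (number of primitives),
#'   `element_size` (length-2 size range in pixels) and `noise_sd`.
#' @export
texture_params <- function(class) {
  assert_class_label(class)
  defaults <- list(
    ADI  = list(base = c(190, 130, 165), element_color = c(245, 245, 245),
                accent = c(215, 150, 180), element_density = 10,
                element_size = c(16, 30), noise_sd = 8),
    BACK = list(base = c(246, 246, 246), element_color = NULL, accent = NULL,
                element_density = 0, element_size = c(0, 0), noise_sd = 3),
    DEB  = list(base = c(175, 150, 158), element_color = c(140, 130, 135),
                accent = NULL, element_density = 25,
                element_size = c(3, 8), noise_sd = 35),
    LYM  = list(base = c(205, 175, 195), element_color = c(45, 45, 105),
                accent = NULL, element_density = 160,
                element_size = c(2, 4), noise_sd = 8),
    MUC  = list(base = c(160, 195, 215), element_color = c(175, 210, 225),
                accent = NULL, element_density = 6,
                element_size = c(25, 60), noise_sd = 5),
    MUS  = list(base = c(185, 125, 155), element_color = c(150, 90, 125),
                accent = NULL, element_density = 0,
                element_size = c(10, 18), noise_sd = 8),
    NORM = list(base = c(215, 170, 195), element_color = c(150, 100, 160),
                accent = c(225, 195, 215), element_density = 9,
                element_size = c(14, 24), noise_sd = 8),
    STR  = list(base = c(210, 160, 185), element_color = c(180, 110, 150),
                accent = NULL, element_density = 0,
                element_size = c(8, 14), noise_sd = 8),
    TUM  = list(base = c(200, 150, 185), element_color = c(125, 70, 150),
                accent = NULL, element_density = 40,
                element_size = c(8, 16), noise_sd = 8)
  )
  c(list(class = class), defaults[[class]])
}

# Painters operate on an environment holding channel matrices r, g, b and
# restrict mask evaluation to the primitive's bounding box, which keeps
# tile generation fast enough to synthesize training sets on one CPU.

paint_box <- function(env, y_rng, x_rng, mask, rgb) {
  if (!any(mask)) return(invisible(NULL))
  env$r[y_rng, x_rng][mask] <- rgb[1]
  env$g[y_rng, x_rng][mask] <- rgb[2]
  env$b[y_rng, x_rng][mask] <- rgb[3]
  invisible(NULL)
}

local_grid <- function(px, cy, cx, half) {
  y_rng <- max(1, floor(cy - half)):min(px, ceiling(cy + half))
  x_rng <- max(1, floor(cx - half)):min(px, ceiling(cx + half))
  list(
    y_rng = y_rng, x_rng = x_rng,
    yy = matrix(y_rng, nrow = length(y_rng), ncol = length(x_rng)),
    xx = matrix(x_rng, nrow = length(y_rng), ncol = length(x_rng),
                byrow = TRUE)
  )
}

paint_disc <- function(env, px, cy, cx, rad, rgb) {
  lg <- local_grid(px, cy, cx, rad)
  mask <- (lg$yy - cy)^2 + (lg$xx - cx)^2 <= rad^2
  paint_box(env, lg$y_rng, lg$x_rng, mask, rgb)
}

paint_ring <- function(env, px, cy, cx, rad, thickness, rgb) {
  lg <- local_grid(px, cy, cx, rad)
  d2 <- (lg$yy - cy)^2 + (lg$xx - cx)^2
  mask <- d2 <= rad^2 & d2 > (rad - thickness)^2
  paint_box(env, lg$y_rng, lg$x_rng, mask, rgb)
}

paint_ellipse <- function(env, px, cy, cx, a, b, theta, rgb) {
  lg <- local_grid(px, cy, cx, max(a, b))
  u <- (lg$xx - cx) * cos(theta) + (lg$yy - cy) * sin(theta)
  v <- -(lg$xx - cx) * sin(theta) + (lg$yy - cy) * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  paint_box(env, lg$y_rng, lg$x_rng, mask, rgb)
}

paint_stripes <- function(env, px, theta, period, phase, rgb, duty = 0.45) {
  yy <- matrix(seq_len(px), nrow = px, ncol = px)
  xx <- matrix(seq_len(px), nrow = px, ncol = px, byrow = TRUE)
  proj <- cos(theta) * xx + sin(theta) * yy
  mask <- sin(2 * pi * proj / period + phase) > cos(pi * duty)
  env$r[mask] <- rgb[1]
  env$g[mask] <- rgb[2]
  env$b[mask] <- rgb[3]
  invisible(NULL)
}

#' Generate one synthetic tissue tile
#'
#' Draws a 224x224 RGB tile of the requested tissue class using the
#' parametric textures of [texture_params()]. Identical `class`, `seed`,
#' and parameters produce bit-identical tiles; the caller's RNG state is
#' left untouched.
#'
#' @param class One of [tissue_classes()].
#' @param seed Integer seed for this tile.
#' @param tile_px Side length in pixels (default 224).
#' @param params Texture parameters; defaults to `texture_params(class)`.
#'   Supplying a modified copy overrides densities, sizes, colors or noise.
#' @return Numeric `tile_px x tile_px x 3` array with values in 0..255.
#' @export
#' @examples
#' tile <- simulate_tile("ADI", seed = 1)
#' mean(tile) # mean gray value, well below the background threshold of 200
simulate_tile <- function(class, seed = 1L, tile_px = 224L,
                          params = texture_params(class)) {
  assert_class_label(class)
  if (!identical(params$class, class)) {
    stop("params$class does not match `class`", call. = FALSE)
  }
  if (params$element_density < 0) stop("element_density must be >= 0", call. = FALSE)
  px <- as.integer(tile_px)
  with_local_seed(seed, {
    env <- new.env(parent = emptyenv())
    env$r <- matrix(params$base[1], px, px)
    env$g <- matrix(params$base[2], px, px)
    env$b <- matrix(params$base[3], px, px)
    n <- params$element_density
    sz <- params$element_size
    switch(class,
      ADI = for (i in seq_len(n)) {
        cy <- runif(1, 1, px); cx <- runif(1, 1, px)
        rad <- runif(1, sz[1], sz[2])
        paint_disc(env, px, cy, cx, rad + 3, params$accent)
        paint_disc(env, px, cy, cx, rad, params$element_color)
      },
      BACK = NULL,
      DEB = for (i in seq_len(n)) {
        paint_disc(env, px, runif(1, 1, px), runif(1, 1, px),
                   runif(1, sz[1], sz[2]), params$element_color)
      },
      LYM = for (i in seq_len(n)) {
        paint_disc(env, px, runif(1, 1, px), runif(1, 1, px),
                   runif(1, sz[1], sz[2]), params$element_color)
      },
      MUC = for (i in seq_len(n)) {
        paint_disc(env, px, runif(1, 1, px), runif(1, 1, px),
                   runif(1, sz[1], sz[2]), params$element_color)
      },
      MUS = paint_stripes(env, px,
                          theta = pi / 2 + runif(1, -pi / 12, pi / 12),
                          period = runif(1, sz[1], sz[2]),
                          phase = runif(1, 0, 2 * pi),
                          rgb = params$element_color),
      NORM = for (i in seq_len(n)) {
        cy <- runif(1, 1, px); cx <- runif(1, 1, px)
        rad <- runif(1, sz[1], sz[2])
        paint_disc(env, px, cy, cx, rad - 4, params$accent)
        paint_ring(env, px, cy, cx, rad, 4, params$element_color)
      },
      STR = paint_stripes(env, px,
                          theta = runif(1, -pi / 12, pi / 12),
                          period = runif(1, sz[1], sz[2]),
                          phase = runif(1, 0, 2 * pi),
                          rgb = params$element_color),
      TUM = for (i in seq_len(n)) {
        paint_ellipse(env, px, runif(1, 1, px), runif(1, 1, px),
                      a = runif(1, sz[1], sz[2]),
                      b = runif(1, sz[1] / 2, sz[2] / 2),
                      theta = runif(1, 0, pi),
                      rgb = params$element_color)
      }
    )
    out <- array(c(env$r, env$g, env$b), dim = c(px, px, 3))
    noise <- array(stats::rnorm(px * px * 3, 0, params$noise_sd),
                   dim = c(px, px, 3))
    clamp255(out + noise)
  })
}
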