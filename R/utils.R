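# Internal helpers shared across modules.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for item `index` of a stream seeded with `seed`.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

assert_rgb_tile <- function(pixels, what = "tile") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop(what, " must be an H x W x 3 pixel array", call. = FALSE)
  }
  invisible(pixels)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
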