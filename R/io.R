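# Reading and writing the package's on-disk formats: PNG slides with a
# JSON sidecar (mpp + optional ground-truth grid), TSV tables, GMT gene sets.

#' Write a slide to PNG with a JSON sidecar
#'
#' The pixel array goes to `<path>.png`; resolution (mpp) and, for
#' synthetic slides, the ground-truth label grid go to `<path>.json`.
#'
#' @param x A [slide_image()] or a `"synthetic_slide"` (whose label grid is
#'   then stored in the sidecar).
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_slide <- function(x, path) {
  labels <- NULL
  if (inherits(x, "synthetic_slide")) {
    labels <- x$labels
    x <- x$slide
  }
  stopifnot(inherits(x, "slide_image"))
  png::writePNG(x$pixels / 255, paste0(path, ".png"))
  sidecar <- list(slide_id = x$slide_id, mpp = x$mpp)
  if (!is.null(labels)) sidecar$labels <- labels
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a slide written by [write_slide()]
#'
#' @param path Path without extension (expects `<path>.png` and
#'   `<path>.json`).
#' @return A [slide_image()]; if the sidecar holds a ground-truth grid it
#'   is attached as the `"labels"` attribute.
#' @export
read_slide <- function(path) {
  px <- png::readPNG(paste0(path, ".png"))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  px <- px[, , 1:3, drop = FALSE] * 255
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- slide_image(px, mpp = sidecar$mpp,
                     slide_id = sidecar$slide_id %||% basename(path))
  if (!is.null(sidecar$labels)) attr(out, "labels") <- sidecar$labels
  out
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then member genes. Sets
#' with duplicate members are deduplicated with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate genes in set ", f[1], "; deduplicated", call. = FALSE)
      members <- unique(members)
    }
    members
  })
  stats::setNames(sets, vapply(fields, `[`, "", 1L))
}

#' Write gene sets to GMT
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  description <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' Genes in rows (first column `gene`), samples in columns.
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path, call. = FALSE)
  m
}

#' @rdname read_expression_tsv
#' @param expr Numeric genes x samples matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}
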