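#' Canonical nine-class tissue labels
#'
#' The nine colorectal tissue classes used throughout the package, in fixed
#' alphabetical order: ADI (adipose), BACK (background), DEB (debris),
#' LYM (lymphocyte aggregates), MUC (mucus), MUS (smooth muscle),
#' NORM (normal colon mucosa), STR (cancer-associated stroma),
#' TUM (tumor epithelium). Class indices 0-8 follow this order and are
#' immutable; all probability matrices and count tables use it.
#'
#' @return Character vector of the nine class labels.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  c("ADI", "BACK", "DEB", "LYM", "MUC", "MUS", "NORM", "STR", "TUM")
}

assert_class_label <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% tissue_classes()) {
    stop("unknown tissue class label: ", paste(label, collapse = ", "),
         " (expected one of ", paste(tissue_classes(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(label)
}

#' Assign class labels from a probability matrix
#'
#' Each tile's label is the class with maximum predicted probability
#' (argmax). Ties are broken toward the lowest class index, so a degenerate
#' uniform probability vector yields "ADI".
#'
#' @param probs Numeric matrix, one row per tile, nine columns ordered as
#'   [tissue_classes()]. Rows must be non-negative and sum to 1 within 1e-6.
#' @return Character vector of labels, one per row.
#' @export
label_from_probs <- function(probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 9L) stop("probability matrix must have 9 columns", call. = FALSE)
  if (nrow(probs) == 0L) return(character(0))
  if (any(probs < -1e-9)) stop("probabilities must be non-negative", call. = FALSE)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("probability rows must sum to 1 within 1e-6", call. = FALSE)
  }
  tissue_classes()[max.col(probs, ties.method = "first")]
}
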