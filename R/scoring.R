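#' Per-slide tissue composition from tile predictions
#'
#' Counts the classified tiles of one slide per tissue class. The total is
#' preserved exactly: counts over the nine classes sum to the number of
#' prediction rows.
#'
#' @param predictions Prediction tibble from [classify_tiles()]; all rows
#'   must share one `slide_id`.
#' @param n_background_removed Count of tiles removed by the background
#'   pre-filter, carried along for reporting (default 0).
#' @return One-row-per-class tibble: `slide_id`, `label`, `n`, with
#'   attribute `n_background_removed`. All nine classes appear, zero-filled.
#' @export
#' @examples
#' preds <- tibble::tibble(slide_id = "s1", label = c("TUM", "TUM", "ADI"))
#' slide_composition(preds)
slide_composition <- function(predictions, n_background_removed = 0L) {
  sid <- unique(predictions$slide_id)
  if (length(sid) > 1L) {
    stop("predictions mix slide_ids: ", paste(sid, collapse = ", "),
         call. = FALSE)
  }
  if (length(sid) == 0L) sid <- NA_character_
  counts <- table(factor(predictions$label, levels = tissue_classes()))
  out <- tibble::tibble(
    slide_id = sid,
    label = tissue_classes(),
    n = as.integer(counts)
  )
  attr(out, "n_background_removed") <- as.integer(n_background_removed)
  out
}

#' ADI score of a composition
#'
#' The adipose score is the fraction of classified tiles carrying the ADI
#' label: `n_ADI / n_classified`. All classified tiles count in the
#' denominator, including any the model itself labels BACK (tiles removed
#' by the background pre-filter never reach classification and are not
#' counted); set `drop_back = TRUE` to exclude model-labeled BACK tiles
#' instead. A slide with zero classified tiles has no defined score and
#' returns `NA`, never 0.
#'
#' @param composition Tibble from [slide_composition()] (or any tibble with
#'   `label` and `n` columns for one slide).
#' @param drop_back Exclude model-labeled BACK tiles from the denominator
#'   (default FALSE).
#' @return Single numeric score in `[0, 1]`, or `NA_real_`.
#' @export
#' @examples
#' comp <- tibble::tibble(label = c("ADI", "TUM"), n = c(200L, 800L))
#' adi_score(comp) # 0.2
adi_score <- function(composition, drop_back = FALSE) {
  n_adi <- sum(composition$n[composition$label == "ADI"])
  denom <- if (drop_back) {
    sum(composition$n[composition$label != "BACK"])
  } else {
    sum(composition$n)
  }
  if (denom == 0L) return(NA_real_)
  n_adi / denom
}

#' Aggregate slide compositions into per-patient scores
#'
#' Pools tile counts across each patient's slides (weighting slides by
#' their tile counts), then computes class proportions and the ADI score
#' from the pooled counts. Pooling counts is order-invariant and equals
#' scoring the concatenated prediction stream.
#'
#' @param compositions Tibble of stacked [slide_composition()] rows
#'   (`slide_id`, `label`, `n`).
#' @param slide_to_patient Tibble mapping `slide_id` to `patient_id`; if
#'   NULL, each slide is its own patient.
#' @param drop_back Passed to the score denominator as in [adi_score()].
#' @return Patient score tibble: `patient_id`, `n_tiles`, `adi`, and nine
#'   proportion columns `prop_ADI` ... `prop_TUM` (proportions sum to 1
#'   whenever `n_tiles > 0`; `adi` is `NA` otherwise).
#' @export
aggregate_patient_scores <- function(compositions, slide_to_patient = NULL,
                                     drop_back = FALSE) {
  df <- tibble::as_tibble(compositions)
  if (is.null(slide_to_patient)) {
    df$patient_id <- df$slide_id
  } else {
    df <- dplyr::left_join(df, slide_to_patient, by = "slide_id")
    if (anyNA(df$patient_id)) stop("unmapped slide_id", call. = FALSE)
  }
  pooled <- df |>
    dplyr::group_by(.data$patient_id, .data$label) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  wide <- pooled |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (cl in setdiff(tissue_classes(), names(wide))) wide[[cl]] <- 0L
  counts <- as.matrix(wide[, tissue_classes()])
  n_tiles <- rowSums(counts)
  denom <- if (drop_back) n_tiles - counts[, "BACK"] else n_tiles
  props <- counts / ifelse(n_tiles > 0, n_tiles, NA_real_)
  colnames(props) <- paste0("prop_", tissue_classes())
  out <- tibble::tibble(
    patient_id = wide$patient_id,
    n_tiles = as.integer(n_tiles),
    adi = ifelse(denom > 0, counts[, "ADI"] / denom, NA_real_)
  )
  dplyr::bind_cols(out, tibble::as_tibble(props))
}

#' Correlate patient scores with a covariate
#'
#' Spearman rank correlation (default) between the ADI score and a
#' clinical covariate such as BMI, with the asymptotic p-value. Pairs with
#' a missing value in either variable are dropped.
#'
#' @param data Data frame of patients.
#' @param score,covariate Column names (strings) of the two variables.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble: `rho`, `p`, `n`, `method`. `rho` is `NA` when
#'   either variable is constant after dropping missing pairs.
#' @export
correlate_scores <- function(data, score = "adi", covariate = "bmi",
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- data[[score]]
  y <- data[[covariate]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = length(x),
                          method = method))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
                 method = method)
}
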