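#' Fit the reference nine-class tissue classifier
#'
#' A multinomial logistic regression on the summary features of
#' [extract_tile_features()], standing in — behind the same prediction
#' interface — for a transfer-learned deep CNN. A stratified 20% split is
#' held out and the held-out accuracy stored with the model. The fit is
#' deterministic under `seed`.
#'
#' @param x Either a tibble with a `label` column and a `pixels`
#'   list-column (features are extracted first), or a feature table as
#'   produced by [simulate_tile_features()].
#' @param seed Integer seed for the holdout split and optimizer start.
#' @param holdout Held-out fraction for the accuracy estimate
#'   (default 0.2; 0 disables).
#' @param min_per_class Minimum training tiles required per class
#'   (default 20).
#' @return An object of class `"tissue_classifier"`: the fitted model,
#'   feature centering/scaling, and training metadata (`n_tiles`, `seed`,
#'   `holdout_accuracy`).
#' @export
#' @examples
#' \donttest{
#' feats <- simulate_tile_features(25, seed = 1)
#' model <- fit_tissue_classifier(feats, seed = 1)
#' model$holdout_accuracy
#' }
fit_tissue_classifier <- function(x, seed = 1L, holdout = 0.2,
                                  min_per_class = 20L) {
  if (!is.data.frame(x) || !"label" %in% names(x)) {
    stop("x must be a data frame with a 'label' column", call. = FALSE)
  }
  if ("pixels" %in% names(x)) x <- extract_tile_features(x)
  missing_classes <- setdiff(tissue_classes(), unique(x$label))
  if (length(missing_classes) > 0) {
    stop("missing training tiles for class(es): ",
         paste(missing_classes, collapse = ", "), call. = FALSE)
  }
  counts <- table(x$label)
  if (any(counts < min_per_class)) {
    stop("need at least ", min_per_class, " tiles per class", call. = FALSE)
  }
  feat_cols <- setdiff(names(x), "label")
  X <- as.matrix(x[, feat_cols])
  y <- factor(x$label, levels = tissue_classes())

  with_local_seed(seed, {
    idx_test <- integer(0)
    if (holdout > 0) {
      idx_test <- unlist(lapply(split(seq_along(y), y), function(ii) {
        sample(ii, max(1L, round(length(ii) * holdout)))
      }), use.names = FALSE)
    }
    idx_train <- setdiff(seq_along(y), idx_test)

    center <- colMeans(X[idx_train, , drop = FALSE])
    scale_ <- apply(X[idx_train, , drop = FALSE], 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
    Z <- sweep(sweep(X, 2, center), 2, scale_, "/")

    train_df <- data.frame(label = y[idx_train], Z[idx_train, , drop = FALSE])
    fit <- nnet::multinom(label ~ ., data = train_df, maxit = 1000,
                          trace = FALSE, MaxNWts = 5000)

    acc <- NA_real_
    if (length(idx_test) > 0) {
      test_df <- data.frame(Z[idx_test, , drop = FALSE])
      pred <- predict(fit, newdata = test_df, type = "class")
      acc <- mean(as.character(pred) == as.character(y[idx_test]))
    }
    structure(
      list(fit = fit, feat_cols = feat_cols, center = center, scale = scale_,
           n_tiles = length(idx_train), seed = as.integer(seed),
           holdout_accuracy = acc),
      class = "tissue_classifier"
    )
  })
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat(sprintf(
    "<tissue_classifier: multinomial logit on %d features, %d training tiles, held-out accuracy %.3f>\n",
    length(x$feat_cols), x$n_tiles, x$holdout_accuracy))
  invisible(x)
}

predict_probs <- function(model, features) {
  Z <- sweep(sweep(as.matrix(features[, model$feat_cols, drop = FALSE]),
                   2, model$center), 2, model$scale, "/")
  if (!is.null(model$fit)) {
    p <- predict(model$fit, newdata = data.frame(Z), type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  } else {
    # reconstructed from serialized multinomial coefficients:
    # rows of B are non-baseline classes, baseline = first class (ADI)
    B <- model$coefficients
    eta <- cbind(1, Z) %*% t(B)
    eta <- pmin(eta, 700)
    expeta <- cbind(1, exp(eta))
    p <- expeta / rowSums(expeta)
    colnames(p) <- c(setdiff(tissue_classes(), rownames(B)), rownames(B))
  }
  p <- p[, tissue_classes(), drop = FALSE]
  p / rowSums(p)
}

#' Classify tiles into the nine tissue classes
#'
#' Runs the classifier over a stream of tiles, preserving order, and
#' assigns each tile the class with maximum predicted probability (ties
#' broken toward the lowest class index; see [label_from_probs()]).
#'
#' @param tiles Tibble from [tile_slide()] (columns `slide_id`, `row`,
#'   `col`, `pixels`) or any tibble with a `pixels` list-column.
#' @param model A `"tissue_classifier"`.
#' @return Prediction tibble: `slide_id`, `row`, `col`, `label`, and nine
#'   probability columns `p_ADI` ... `p_TUM`, one row per tile in input
#'   order.
#' @export
classify_tiles <- function(tiles, model) {
  stopifnot(inherits(model, "tissue_classifier"))
  id_cols <- intersect(c("slide_id", "row", "col"), names(tiles))
  if (nrow(tiles) == 0L) {
    out <- tibble::as_tibble(tiles[, id_cols, drop = FALSE])
    out$label <- character(0)
    for (cl in tissue_classes()) out[[paste0("p_", cl)]] <- numeric(0)
    return(out)
  }
  feats <- do.call(rbind, purrr::map(tiles$pixels, extract_tile_features))
  probs <- predict_probs(model, tibble::as_tibble(feats))
  out <- tibble::as_tibble(tiles[, id_cols, drop = FALSE])
  out$label <- label_from_probs(probs)
  colnames(probs) <- paste0("p_", tissue_classes())
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' Save / load a tissue classifier as portable text
#'
#' Serializes the model (multinomial coefficients, feature scaling,
#' metadata) to JSON so that a fitted classifier can travel with results.
#'
#' @param model A `"tissue_classifier"`.
#' @param path File path.
#' @return `path` invisibly; `load_classifier` returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "tissue_classifier"))
  coefs <- stats::coef(model$fit)
  payload <- list(
    coefficients = list(values = unname(coefs), rows = rownames(coefs),
                        cols = colnames(coefs)),
    feat_cols = model$feat_cols,
    center = model$center, scale = model$scale,
    n_tiles = model$n_tiles, seed = model$seed,
    holdout_accuracy = model$holdout_accuracy
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- matrix(as.numeric(payload$coefficients$values),
                  nrow = length(payload$coefficients$rows),
                  dimnames = list(payload$coefficients$rows,
                                  payload$coefficients$cols))
  structure(
    list(coefficients = coefs, feat_cols = payload$feat_cols,
         center = stats::setNames(payload$center, payload$feat_cols),
         scale = stats::setNames(payload$scale, payload$feat_cols),
         n_tiles = payload$n_tiles, seed = payload$seed,
         holdout_accuracy = payload$holdout_accuracy),
    class = c("tissue_classifier_coefs", "tissue_classifier")
  )
}
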