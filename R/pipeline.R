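pipeline_defaults <- function() {
  list(
    paths = list(slides_dir = NULL, survival = NULL, expression = NULL,
                 gene_sets = NULL, out_dir = "histoadi_out"),
    tiling = list(tile_px = 224L, target_mpp = 0.5,
                  background_threshold = 200),
    classifier = list(type = "reference", n_train_per_class = 50L,
                      model_path = NULL),
    scoring = list(drop_back = FALSE),
    stratification = list(method = "cutpoint", minprop = 0.1),
    enrichment = list(alpha = 0.25, n_perm = 1000L, test = "welch",
                      normalize = FALSE),
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults (tile side 224 px, working resolution 0.5 mpp,
#' background gray threshold 200, 1000 enrichment permutations), checks
#' ranges, and rejects unknown keys. The input may be a nested list or the
#' path to a YAML file with the same structure.
#'
#' @param config Nested list or YAML file path; `NULL` or an empty list
#'   yields all defaults.
#' @return Validated config list of class `"pipeline_config"`.
#' @export
#' @examples
#' validate_config(list(tiling = list(background_threshold = 190)))$tiling
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- defaults
  for (section in names(config)) {
    if (section == "seed") {
      out$seed <- as.integer(config$seed)
      next
    }
    unknown <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(unknown) > 0) {
      stop("unknown config key(s) in '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out[[section]] <- utils::modifyList(defaults[[section]],
                                        config[[section]])
  }
  with(out$tiling, {
    if (tile_px < 1) stop("tile_px must be >= 1", call. = FALSE)
    if (target_mpp <= 0) stop("target_mpp must be > 0", call. = FALSE)
    if (background_threshold < 0 || background_threshold > 255) {
      stop("background_threshold must be in [0, 255]", call. = FALSE)
    }
  })
  if (out$stratification$minprop <= 0 || out$stratification$minprop >= 0.5) {
    stop("minprop must be in (0, 0.5)", call. = FALSE)
  }
  if (!out$stratification$method %in% c("cutpoint", "median")) {
    stop("stratification method must be 'cutpoint' or 'median'", call. = FALSE)
  }
  if (out$enrichment$n_perm < 10) stop("n_perm must be >= 10", call. = FALSE)
  if (!out$enrichment$test %in% c("welch", "mannwhitney")) {
    stop("enrichment test must be 'welch' or 'mannwhitney'", call. = FALSE)
  }
  structure(out, class = c("pipeline_config", "list"))
}

#' Simulate a complete synthetic study
#'
#' Writes to `dir` everything [run_pipeline()] consumes, with coherent
#' ground truth across modalities: a cohort from [simulate_cohort()]
#' (hazard stepping at the true cutpoint), one mosaic slide per patient
#' whose interior adipose fraction equals the patient's ADI draw, an
#' expression matrix with gene sets shifted in the high-ADI patients, and
#' the gene sets as GMT.
#'
#' @param dir Output directory (created if missing).
#' @param n_patients Number of patients / slides.
#' @param grid_rows,grid_cols Mosaic size per slide.
#' @param tile_px Tile side in pixels (default 224).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cohort()].
#' @return Invisibly, a list with the cohort, per-slide ground truth and
#'   file paths.
#' @export
simulate_study <- function(dir, n_patients = 40, grid_rows = 8,
                           grid_cols = 8, tile_px = 224L, seed = 1L, ...) {
  dir.create(file.path(dir, "slides"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- simulate_cohort(n_patients = n_patients, seed = seed, ...)
  true_cut <- attr(cohort, "true_cutpoint")
  # remaining tissue split over the non-ADI foreground classes
  rest <- c(TUM = 0.4, STR = 0.2, NORM = 0.15, LYM = 0.1, MUS = 0.08,
            MUC = 0.05, DEB = 0.02)
  slides <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    adi <- cohort$adi[i]
    comp <- c(ADI = adi, rest * (1 - adi))
    sl <- simulate_slide(grid_rows, grid_cols, comp,
                         tile_px = tile_px,
                         seed = derive_seed(seed, 1000L + i),
                         slide_id = cohort$patient_id[i])
    write_slide(sl, file.path(dir, "slides", cohort$patient_id[i]))
    slides[[i]] <- sl$composition
  }
  surv_path <- file.path(dir, "survival.tsv")
  readr::write_tsv(cohort[, c("patient_id", "time", "event", "sex",
                              "histology", "bmi")], surv_path)
  group <- ifelse(cohort$adi > true_cut, "high", "low")
  ex <- simulate_expression(n_samples = n_patients, group = group,
                            seed = derive_seed(seed, 77L))
  colnames(ex$expr) <- cohort$patient_id
  expr_path <- file.path(dir, "expression.tsv")
  write_expression_tsv(ex$expr, expr_path)
  gmt_path <- file.path(dir, "gene_sets.gmt")
  write_gmt(ex$gene_sets, gmt_path)
  invisible(list(cohort = cohort, slide_compositions = slides,
                 shifted_sets = ex$shifted_sets,
                 paths = list(slides_dir = file.path(dir, "slides"),
                              survival = surv_path,
                              expression = expr_path,
                              gene_sets = gmt_path)))
}

#' Run the end-to-end ADI pipeline
#'
#' Executes the stages in order — tile, classify, score, stratify
#' survival, enrichment — over the inputs named in the config, writing all
#' intermediate tables (TSV) and a summary (JSON) to the output directory.
#' Stages whose inputs are absent are skipped with a warning (e.g.
#' enrichment without expression data). The run is fully reproducible from
#' the config and seed, both echoed in the returned report.
#'
#' @param config A [validate_config()] input (list, YAML path, or
#'   validated config).
#' @return A `"run_report"` list: `config`, `seed`, `counts` per stage,
#'   `manifest` of written files, `warnings`, `elapsed` seconds, plus the
#'   in-memory results (`scores`, `survival`, `enrichment`).
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t0 <- Sys.time()
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  warnings <- character(0)
  counts <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    manifest <<- c(manifest, path)
    path
  }

  if (is.null(config$paths$slides_dir)) {
    stop("pipeline stage 'tile': no slides_dir configured", call. = FALSE)
  }
  slide_paths <- sub("\\.png$", "",
                     list.files(config$paths$slides_dir,
                                pattern = "\\.png$", full.names = TRUE))
  if (length(slide_paths) == 0) {
    stop("pipeline stage 'tile': no PNG slides in ",
         config$paths$slides_dir, call. = FALSE)
  }

  model <- if (!is.null(config$classifier$model_path)) {
    load_classifier(config$classifier$model_path)
  } else {
    feats <- simulate_tile_features(config$classifier$n_train_per_class,
                                    seed = config$seed)
    fit_tissue_classifier(feats, seed = config$seed)
  }

  reports <- list()
  compositions <- list()
  predictions_all <- list()
  for (sp in slide_paths) {
    slide <- read_slide(sp)
    tiles <- tile_slide(slide,
                        tile_px = config$tiling$tile_px,
                        target_mpp = config$tiling$target_mpp,
                        background_threshold = config$tiling$background_threshold)
    rep_i <- tiling_report(tiles)
    preds <- classify_tiles(tiles, model)
    reports[[sp]] <- rep_i
    predictions_all[[sp]] <- preds
    compositions[[sp]] <- slide_composition(
      preds, n_background_removed = rep_i$removed)
  }
  tiling_tbl <- dplyr::bind_rows(reports)
  emit(tiling_tbl, "tiling_report.tsv")
  emit(dplyr::bind_rows(predictions_all), "predictions.tsv")
  counts$slides <- length(slide_paths)
  counts$tiles_total <- sum(tiling_tbl$total)
  counts$tiles_kept <- sum(tiling_tbl$kept)

  scores <- aggregate_patient_scores(dplyr::bind_rows(compositions),
                                     drop_back = config$scoring$drop_back)
  emit(scores, "patient_scores.tsv")
  counts$patients <- nrow(scores)

  surv_res <- NULL
  if (!is.null(config$paths$survival) && file.exists(config$paths$survival)) {
    surv_tbl <- readr::read_tsv(config$paths$survival,
                                show_col_types = FALSE)
    surv_res <- stratify_survival(
      scores, surv_tbl,
      method = config$stratification$method,
      minprop = config$stratification$minprop)
    emit(surv_res$km, "km_curves.tsv")
    stats_path <- file.path(out_dir, "survival.json")
    jsonlite::write_json(as.list(glance(surv_res)), stats_path,
                         auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, stats_path)
    counts$events <- sum(surv_res$data$event)
  } else {
    warnings <- c(warnings, "survival table absent: stage skipped")
    warning("survival table absent: stage skipped", call. = FALSE)
  }

  enrich_res <- NULL
  have_expr <- !is.null(config$paths$expression) &&
    file.exists(config$paths$expression) &&
    !is.null(config$paths$gene_sets) &&
    file.exists(config$paths$gene_sets)
  if (have_expr && !is.null(surv_res)) {
    expr <- read_expression_tsv(config$paths$expression)
    sets <- read_gmt(config$paths$gene_sets)
    groups <- stats::setNames(as.character(surv_res$data$group),
                              surv_res$data$patient_id)
    expr <- expr[, intersect(colnames(expr), names(groups)), drop = FALSE]
    ss <- ssgsea_scores(expr, sets, alpha = config$enrichment$alpha,
                        normalize = config$enrichment$normalize)
    cmp <- compare_groups(ss, groups[colnames(expr)],
                          test = config$enrichment$test)
    emit(ss, "ssgsea_scores.tsv")
    emit(cmp, "ssgsea_comparison.tsv")
    # per-gene high-vs-low Welch t statistic as the preranked input
    grp_vec <- groups[colnames(expr)]
    tstat <- apply(expr, 1, function(v) {
      a <- v[grp_vec == "high"]; b <- v[grp_vec == "low"]
      if (stats::sd(v) == 0) 0 else unname(stats::t.test(a, b)$statistic)
    })
    gsea <- gsea_preranked(tstat, sets, n_perm = config$enrichment$n_perm,
                           seed = config$seed)
    emit(gsea, "gsea_preranked.tsv")
    enrich_res <- list(ssgsea = ss, comparison = cmp, gsea = gsea)
    counts$gene_sets <- length(sets)
  } else if (!have_expr) {
    warnings <- c(warnings, "expression or gene sets absent: enrichment skipped")
    warning("expression or gene sets absent: enrichment skipped",
            call. = FALSE)
  }

  report <- structure(
    list(config = unclass(config), seed = config$seed, counts = counts,
         manifest = manifest, warnings = warnings,
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         scores = scores, survival = surv_res, enrichment = enrich_res),
    class = "run_report"
  )
  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(
    list(config = unclass(config), seed = config$seed, counts = counts,
         manifest = report$manifest, warnings = warnings,
         elapsed = report$elapsed),
    report_path, auto_unbox = TRUE, digits = NA, null = "null")
  report$manifest <- c(report$manifest, report_path)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("histoadi pipeline run\n")
  cat("  seed:", x$seed, "\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  cat(sprintf("  %d files written in %.1f s\n", length(x$manifest),
              x$elapsed))
  if (length(x$warnings) > 0) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
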