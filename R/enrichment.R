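#' Single-sample GSEA scores
#'
#' Per-sample pathway activity via the weighted empirical-CDF difference:
#' within each sample, genes are ranked by expression (highest first, ties
#' broken by gene identifier order for determinism); the enrichment score
#' of a set is the sum over the ordered gene list of the difference between
#' the weighted in-set ECDF (weights `rank^alpha`, rank N for the top gene)
#' and the unweighted out-of-set ECDF. Because only ranks enter, the score
#' is invariant to any strictly monotone transform of a sample's
#' expression values.
#'
#' @param expr Numeric genes x samples matrix with gene rownames (a single
#'   named vector is treated as a one-sample matrix).
#' @param gene_sets Named list of gene identifier vectors; each set is
#'   intersected with the expression universe, and sets with fewer than 2
#'   overlapping genes are skipped with a warning.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize If TRUE, divide all scores by the overall
#'   `max - min` score range (GSVA-style normalization; default FALSE).
#' @return Long tibble: `gene_set`, `sample`, `es`.
#' @export
ssgsea_scores <- function(expr, gene_sets, alpha = 0.25, normalize = FALSE) {
  if (is.null(dim(expr))) {
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample1"))
  }
  genes <- rownames(expr)
  if (is.null(genes)) stop("expression matrix needs gene rownames", call. = FALSE)
  if (nrow(expr) < 2L) stop("need >= 2 genes", call. = FALSE)
  n <- nrow(expr)
  keep <- vapply(gene_sets, function(s) sum(unique(s) %in% genes) >= 2, TRUE)
  if (any(!keep)) {
    warning("skipping gene set(s) with < 2 overlapping genes: ",
            paste(names(gene_sets)[!keep], collapse = ", "), call. = FALSE)
  }
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0L) stop("no usable gene sets", call. = FALSE)
  member <- lapply(gene_sets, function(s) genes %in% s)

  score_one <- function(x) {
    ord <- order(-x, genes)        # descending expression, gene-id tie-break
    rank_weight <- (n - seq_len(n) + 1)^alpha
    vapply(member, function(inset) {
      ins <- inset[ord]
      w <- rank_weight * ins
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ins) / sum(!ins)
      sum(p_in - p_out)
    }, 0)
  }
  es <- apply(expr, 2, score_one)
  if (is.null(dim(es))) {
    es <- matrix(es, nrow = length(gene_sets),
                 dimnames = list(names(gene_sets), colnames(expr)))
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  tibble::as_tibble(es, rownames = "gene_set") |>
    tidyr::pivot_longer(-"gene_set", names_to = "sample", values_to = "es")
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score of one set
# against a ranked statistic vector (descending order assumed).
gsea_running_es <- function(stat_sorted, inset_sorted, weight = 1) {
  hit <- abs(stat_sorted)^weight * inset_sorted
  n_r <- sum(hit)
  n_out <- sum(!inset_sorted)
  if (n_r == 0 || n_out == 0) return(0)
  running <- cumsum(hit / n_r - (!inset_sorted) / n_out)
  unname(running[which.max(abs(running))])
}

#' Preranked gene-set enrichment analysis
#'
#' Classical weighted running-sum GSEA on a preranked gene list: the
#' enrichment score is the maximum deviation from zero of the running sum
#' that increments by `|stat|^weight` (normalized) at in-set genes and
#' decrements by `1/(N - |S|)` at out-of-set genes. Significance comes
#' from gene-label permutation: `p = (1 + #{|ES*| >= |ES|}) / (1 + n_perm)`
#' (two-sided, never exactly 0), reproducible under `seed`.
#'
#' @param stats Named numeric vector of per-gene ranking statistics
#'   (e.g. a high-vs-low-ADI differential statistic).
#' @param gene_sets Named list of gene sets (or a single character vector).
#' @param n_perm Number of gene-label permutations (default 1000, >= 10).
#' @param weight Running-sum weight exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param seed Integer seed for the permutations.
#' @return Tibble of class `"gsea_result"`: `gene_set`, `size` (overlap
#'   with the universe), `es`, `direction` (sign of `es`), `p`, `n_perm`.
#' @export
gsea_preranked <- function(stats, gene_sets, n_perm = 1000, weight = 1,
                           seed = 1L) {
  if (n_perm < 10) stop("n_perm must be >= 10", call. = FALSE)
  if (is.null(names(stats))) stop("stats must be a named vector", call. = FALSE)
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (any(!is.finite(stats))) stop("ranking statistics must be finite", call. = FALSE)
  genes <- names(stats)
  ord <- order(-stats, genes)
  s_sorted <- stats[ord]
  g_sorted <- genes[ord]
  n <- length(stats)

  with_local_seed(seed, {
    perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
    rows <- purrr::imap(gene_sets, function(set, name) {
      inset <- g_sorted %in% set
      size <- sum(inset)
      if (size < 1 || size >= n) {
        return(tibble::tibble(gene_set = name, size = size, es = NA_real_,
                              direction = NA_real_, p = NA_real_,
                              n_perm = as.integer(n_perm)))
      }
      es <- gsea_running_es(s_sorted, inset, weight)
      null_es <- vapply(perms, function(pp) {
        gsea_running_es(s_sorted, inset[pp], weight)
      }, 0)
      p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
      tibble::tibble(gene_set = name, size = size, es = es,
                     direction = sign(es), p = p,
                     n_perm = as.integer(n_perm))
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("gsea_result", class(out))
    out
  })
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare pathway or immune scores between two groups
#'
#' Row-wise two-sided comparison of score values between two sample
#' groups — Welch's t-test by default, Mann-Whitney U (Wilcoxon rank-sum)
#' by flag — followed by Benjamini-Hochberg adjustment across rows and
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param scores Long tibble (`gene_set`, `sample`, `es`) as returned by
#'   [ssgsea_scores()], or a numeric features x samples matrix.
#' @param groups Named character vector (names = samples) or tibble with
#'   `sample` and `group` columns; exactly two groups, each with >= 2
#'   samples.
#' @param test `"welch"` (default) or `"mannwhitney"`.
#' @return Tibble: `gene_set`, `statistic` (mean difference, first group
#'   minus second), `p`, `q` (BH), `stars`. Constant rows get `p = 1` with
#'   a warning.
#' @export
compare_groups <- function(scores, groups, test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  if (is.matrix(scores)) {
    scores <- tibble::as_tibble(scores, rownames = "gene_set") |>
      tidyr::pivot_longer(-"gene_set", names_to = "sample", values_to = "es")
  }
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample)
  }
  df <- dplyr::mutate(scores, group = unname(groups[.data$sample]))
  if (anyNA(df$group)) stop("samples missing from `groups`", call. = FALSE)
  lev <- sort(unique(df$group))
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  counts <- table(unique(df[, c("sample", "group")])$group)
  if (any(counts < 2)) stop("each group needs >= 2 samples", call. = FALSE)

  warned <- FALSE
  out <- df |>
    dplyr::group_by(.data$gene_set) |>
    dplyr::summarise(
      statistic = mean(.data$es[.data$group == lev[1]]) -
        mean(.data$es[.data$group == lev[2]]),
      p = {
        a <- .data$es[.data$group == lev[1]]
        b <- .data$es[.data$group == lev[2]]
        if (stats::sd(c(a, b)) == 0) {
          warned <<- TRUE
          1
        } else if (test == "welch") {
          stats::t.test(a, b)$p.value
        } else {
          stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
        }
      },
      .groups = "drop"
    )
  if (warned) warning("constant score row(s): p set to 1", call. = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- significance_stars(out$p)
  out
}
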