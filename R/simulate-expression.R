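#' Simulate an expression matrix with planted gene-set shifts
#'
#' Generates a genes-by-samples matrix of Gaussian baseline expression and
#' adds a constant mean shift to the genes of selected sets in the
#' high-ADI samples. This plants a known enrichment signal so that ssGSEA
#' scoring, preranked GSEA and group comparisons can be validated against
#' ground truth.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_samples Number of samples; `group` assigns each to
#'   `"high"`/`"low"` (default: first half high).
#' @param gene_sets Named list of gene identifier vectors; defaults to
#'   `n_sets` disjoint sets of size `set_size` carved from the universe.
#' @param shifted_sets Named numeric vector mapping set name to the mean
#'   shift added to its genes in high-ADI samples (default: first set +2).
#' @param noise_sd Standard deviation of the baseline noise (default 1).
#' @param group Optional character vector of `"high"`/`"low"` per sample.
#' @param n_sets,set_size Used only when `gene_sets` is NULL.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_expression"` with `expr` (numeric
#'   genes x samples matrix with gene rownames and sample colnames),
#'   `gene_sets`, `shifted_sets` and `group`.
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 100, n_samples = 10, seed = 1)
#' dim(sim$expr)
simulate_expression <- function(n_genes = 1000, n_samples = 100,
                                gene_sets = NULL, shifted_sets = NULL,
                                noise_sd = 1, group = NULL,
                                n_sets = 5, set_size = 20, seed = 1L) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (anyDuplicated(genes)) stop("duplicate gene ids", call. = FALSE)
  if (is.null(gene_sets)) {
    if (n_sets * set_size > n_genes) {
      stop("gene universe too small for requested sets", call. = FALSE)
    }
    gene_sets <- stats::setNames(
      lapply(seq_len(n_sets), function(k) {
        genes[((k - 1) * set_size + 1):(k * set_size)]
      }),
      sprintf("SET_%d", seq_len(n_sets))
    )
  }
  if (!all(unlist(gene_sets) %in% genes)) {
    stop("gene sets must be subsets of the gene universe", call. = FALSE)
  }
  if (max(lengths(gene_sets)) > n_genes) {
    stop("n_genes must be >= the largest set size", call. = FALSE)
  }
  if (is.null(shifted_sets)) {
    shifted_sets <- stats::setNames(2, names(gene_sets)[1])
  }
  if (!all(names(shifted_sets) %in% names(gene_sets))) {
    stop("shifted_sets must name existing gene sets", call. = FALSE)
  }
  if (is.null(group)) {
    group <- rep(c("high", "low"), c(ceiling(n_samples / 2),
                                     floor(n_samples / 2)))
  }
  stopifnot(length(group) == n_samples, all(group %in% c("high", "low")))
  samples <- sprintf("s%03d", seq_len(n_samples))

  expr <- with_local_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                nrow = n_genes, dimnames = list(genes, samples))
    for (set in names(shifted_sets)) {
      idx <- match(gene_sets[[set]], genes)
      m[idx, group == "high"] <- m[idx, group == "high"] + shifted_sets[[set]]
    }
    m
  })
  structure(
    list(expr = expr, gene_sets = gene_sets, shifted_sets = shifted_sets,
         group = stats::setNames(group, samples), seed = as.integer(seed)),
    class = "synthetic_expression"
  )
}
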