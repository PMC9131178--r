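test_that("ssGSEA matches direct weighted-ECDF summation on a 10-gene toy", {
  x <- c(g01 = 9.1, g02 = 8.4, g03 = 7.9, g04 = 5.2, g05 = 4.4,
         g06 = 3.3, g07 = 2.8, g08 = 1.9, g09 = 0.7, g10 = 0.1)
  sets <- list(top = c("g01", "g02", "g03"), mid = c("g04", "g06", "g08"))
  res <- ssgsea_scores(matrix(x, ncol = 1, dimnames = list(names(x), "s1")),
                       sets)
  for (nm in names(sets)) {
    expect_equal(res$es[res$gene_set == nm],
                 ssgsea_oracle(x, sets[[nm]]), tolerance = 1e-12)
  }
  # a set at the top of the ranking scores higher than one in the middle
  expect_gt(res$es[res$gene_set == "top"], res$es[res$gene_set == "mid"])
})

test_that("ssGSEA is rank-based: monotone transforms change nothing", {
  sim <- simulate_expression(60, 4, n_sets = 2, set_size = 8, seed = 9)
  sets <- sim$gene_sets
  base <- ssgsea_scores(sim$expr, sets)
  transformed <- ssgsea_scores(exp(sim$expr / 2) + 5, sets)
  expect_equal(base$es, transformed$es, tolerance = 1e-12)
  # identical samples give identical columns
  two <- cbind(sim$expr[, 1], sim$expr[, 1])
  colnames(two) <- c("a", "b")
  rownames(two) <- rownames(sim$expr)
  res2 <- ssgsea_scores(two, sets)
  expect_equal(res2$es[res2$sample == "a"], res2$es[res2$sample == "b"])
})

test_that("raising in-set expression never lowers the set's ssGSEA score", {
  sim <- simulate_expression(80, 1, n_sets = 1, set_size = 10, seed = 4,
                             shifted_sets = c(SET_1 = 0))
  set <- sim$gene_sets$SET_1
  prev <- -Inf
  for (bump in c(0, 0.5, 1, 2, 4)) {
    x <- sim$expr[, 1]
    x[set] <- x[set] + bump
    es <- ssgsea_scores(x, list(s = set))$es
    expect_gte(es, prev - 1e-12)
    prev <- es
  }
})

test_that("small or missing set overlaps are skipped with a warning", {
  x <- stats::setNames(rnorm(20), sprintf("g%02d", 1:20))
  expect_warning(
    res <- ssgsea_scores(x, list(ok = c("g01", "g02", "g03"),
                                 tiny = c("g05", "zzz"))),
    "skipping")
  expect_equal(unique(res$gene_set), "ok")
})

test_that("preranked GSEA: contiguous top block attains the closed-form maximum", {
  n <- 20
  stats_v <- stats::setNames(seq(n, 1), sprintf("g%02d", 1:n))
  set <- sprintf("g%02d", 1:5)
  res <- gsea_preranked(stats_v, list(block = set), n_perm = 50, weight = 0,
                        seed = 1)
  # unweighted running sum peaks right after the block: 5/5 - 0/15 = 1
  expect_equal(res$es, 1, tolerance = 1e-12)
  expect_equal(res$direction, 1)
  # a set at the bottom gives the mirrored negative deviation
  bottom <- sprintf("g%02d", 16:20)
  res2 <- gsea_preranked(stats_v, list(b = bottom), n_perm = 50, weight = 0,
                         seed = 1)
  expect_equal(res2$es, -1, tolerance = 1e-12)
})

test_that("preranked GSEA is seed-reproducible with add-one permutation p", {
  set.seed(2)
  stats_v <- stats::setNames(rnorm(50), sprintf("g%02d", 1:50))
  set <- sample(names(stats_v), 8)
  r1 <- gsea_preranked(stats_v, list(s = set), n_perm = 99, seed = 5)
  r2 <- gsea_preranked(stats_v, list(s = set), n_perm = 99, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  expect_error(gsea_preranked(stats_v, list(s = set), n_perm = 5), "n_perm")
})

test_that("group comparison: exactness, BH monotonicity, planted-shift power", {
  # 3 vs 3 exact Mann-Whitney against exhaustive enumeration
  a <- c(1.2, 3.4, 2.2)
  b <- c(5.1, 4.8, 6.0)
  m <- matrix(c(a, b), nrow = 1,
              dimnames = list("set1", sprintf("s%d", 1:6)))
  groups <- stats::setNames(rep(c("high", "low"), each = 3), colnames(m))
  res <- compare_groups(m, groups, test = "mannwhitney")
  expect_equal(res$p, mannwhitney_exact_oracle(a, b), tolerance = 1e-12)

  # planted shift detected at q < 0.05 with 50 vs 50 samples
  sim <- simulate_expression(n_genes = 300, n_samples = 100, n_sets = 4,
                             set_size = 15, seed = 21,
                             shifted_sets = c(SET_3 = 2))
  ss <- ssgsea_scores(sim$expr, sim$gene_sets)
  cmp <- compare_groups(ss, sim$group)
  expect_lt(cmp$q[cmp$gene_set == "SET_3"], 0.05)
  expect_equal(cmp$stars[cmp$gene_set == "SET_3"], "***")

  # BH never decreases a p-value and preserves ordering
  expect_true(all(cmp$q >= cmp$p - 1e-15))
  expect_true(all(diff(cmp$q[order(cmp$p)]) >= -1e-15))

  # constant rows are p = 1 with a warning
  m2 <- rbind(m, const = rep(1, 6))
  expect_warning(res2 <- compare_groups(m2, groups), "constant")
  expect_equal(res2$p[res2$gene_set == "const"], 1)
})

test_that("gene sets round-trip through GMT", {
  dir <- withr::local_tempdir()
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  p <- file.path(dir, "sets.gmt")
  write_gmt(sets, p)
  expect_identical(read_gmt(p), sets)
  writeLines("dup\tna\tg1\tg1\tg2", p)
  expect_warning(back <- read_gmt(p), "duplicate")
  expect_identical(back$dup, c("g1", "g2"))
})
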