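# Independent oracles and shared fixtures for the test suite.
# The oracles are deliberately naive (per-time loops, direct summation)
# and share no code with the package implementation.

# Product-limit estimate by direct per-time computation.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Two-group log-rank chi-square by a per-event-time hypergeometric loop.
logrank_oracle <- function(time, event, g1) {
  ts <- sort(unique(time[event == 1]))
  ome <- 0
  v <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    ome <- ome + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v > 0) ome^2 / v else 0
}

# ssGSEA enrichment score by direct weighted-ECDF summation.
ssgsea_oracle <- function(x, set, alpha = 0.25) {
  genes <- names(x)
  ord <- order(-x, genes)
  n <- length(x)
  inset <- genes[ord] %in% set
  w <- (n - seq_len(n) + 1)^alpha
  num_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  num_out <- cumsum(!inset) / sum(!inset)
  sum(num_in - num_out)
}

# Exact Mann-Whitney p by exhaustive enumeration of group assignments.
mannwhitney_exact_oracle <- function(a, b) {
  vals <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(vals), n_a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  mu <- n_a * length(b) / 2
  u_all <- apply(idx, 2, function(ii) u_stat(vals[ii], vals[-ii]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# A reference classifier shared across test files (fitted once per run).
.test_cache <- new.env(parent = emptyenv())

test_classifier <- function(n_per_class = 30, seed = 101) {
  key <- paste0("m", n_per_class, "_", seed)
  if (is.null(.test_cache[[key]])) {
    feats <- simulate_tile_features(n_per_class, seed = seed)
    .test_cache[[key]] <- fit_tissue_classifier(feats, seed = seed)
  }
  .test_cache[[key]]
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

with_seed_rnorm <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n)
}
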