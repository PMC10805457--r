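# Shared fixtures and small independent oracles, all generated in code.

# two well-separated groups in q dimensions
make_separated <- function(n_per = 10, q = 2, gap = 8, sigma = 1, seed = 1) {
  withr::with_seed(seed, rbind(
    matrix(rnorm(n_per * q, 0, sigma), n_per, q),
    matrix(rnorm(n_per * q, gap, sigma), n_per, q)))
}

# enumerate all 2-partitions (non-empty) of 1..n; returns list of label vectors
all_two_partitions <- function(n) {
  out <- list()
  for (code in 1:(2^(n - 1) - 1)) {   # fix observation 1 in cluster 1
    bits <- as.integer(intToBits(code))[seq_len(n - 1)]
    out[[length(out) + 1L]] <- c(1L, bits + 1L)
  }
  out
}

# independent WSS (no package helpers)
wss_direct <- function(x, labels) {
  sum(vapply(unique(labels), function(k) {
    rows <- x[labels == k, , drop = FALSE]
    ctr <- colMeans(rows)
    sum(sweep(rows, 2, ctr)^2)
  }, numeric(1)))
}

# fresh spherical test pieces for oracle-based checks
seltest_pieces <- function(x, k, pair, seed) {
  res <- kmeans_sel_test(x, k, pair, sigma = 1, seed = seed)
  line <- perturbation_line(x,
    contrast_vector(final_labels(res$trace), pair[1], pair[2]))
  list(res = res, line = line)
}
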