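# Independent reference implementations ("oracles") used by several test
# files. These deliberately use naive algorithms and never call the package
# internals they are checking.

# Connected components by breadth-first search over an explicit edge list.
bfs_components <- function(nodes, edge_a, edge_b) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- c(edge_b[edge_a == v], edge_a[edge_b == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# Benjamini-Hochberg step-up adjusted p-values, from the definition.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided exact binomial p under the minimum-likelihood rule, by
# enumeration of the full outcome space.
binom_minlike <- function(x, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Score one window of a sequence under a log-odds matrix, base by base.
window_score <- function(mat, window_chars) {
  rows <- match(window_chars, c("A", "C", "G", "T"))
  if (anyNA(rows)) return(NA_real_)
  sum(mat[cbind(rows, seq_along(rows))])
}

# Best score of a sequence over both strands by exhaustive loops, using
# string reversal + complement lookup (independent of the package scanner).
best_score_naive <- function(mat, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- rev(unname(comp[chars]))
  L <- ncol(mat)
  best <- -Inf
  for (s in list(chars, rc)) {
    if (length(s) < L) next
    for (i in seq_len(length(s) - L + 1)) {
      sc <- window_score(mat, s[i:(i + L - 1)])
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  if (is.finite(best)) best else NA_real_
}

# A small ready-made cohort configuration used by several files: two planted
# modules at well-separated loci plus noise peaks.
small_cohort_config <- function(seed, n_samples = 80) {
  sim_config(
    seed = seed, n_samples = n_samples, n_peaks = 16,
    module_spec = tibble::tibble(size = c(5L, 5L), rho = 0.7,
                                 chrom = "chr17",
                                 start = c(10e6, 18e6), span = 1e5))
}
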