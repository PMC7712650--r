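# Fixture builders and independent oracles shared across test files.

make_dataset <- function(values, labels) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, labels)
}

rand_dataset <- function(n_genes, m1, m2, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * (m1 + m2)), nrow = n_genes)
  make_dataset(vals, c(rep(1, m1), rep(-1, m2)))
}

# squared pooled-variance two-sample t statistic (textbook form)
oracle_pooled_t2 <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  ((mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2)))^2
}

# the step-up retain/reject algorithm applied literally: examine the
# ordered p-values from the largest down, rejecting everything at and
# below the first p_(k) <= alpha / (N - k + 1)
oracle_hochberg_reject <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  reject_sorted <- rep(FALSE, n)
  for (k in n:1) {
    if (ps[k] <= alpha / (n - k + 1)) {
      reject_sorted[1:k] <- TRUE
      break
    }
  }
  reject <- logical(n)
  reject[ord] <- reject_sorted
  reject
}

# upper-tail hypergeometric probability by full enumeration of all
# C(N, n) draws; feasible for N <= 12
oracle_hyper_upper <- function(v, N, V, n) {
  draws <- combn(N, n)
  hits <- colSums(draws <= V)      # items 1..V are the successes
  mean(hits >= v)
}

# signed-rank statistic by direct enumeration (independent of the package
# implementation)
oracle_signed_rank <- function(r, q3 = 0.75) {
  dev <- r - q3
  rk <- rank(abs(dev))
  sum(rk[dev > 0])
}
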