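#' Two-group F-statistic (relevance measure)
#'
#' The MRMR relevance of gene i for the case/control contrast:
#' \deqn{F(i) = \frac{M_1(\bar x_{i1} - \bar x_i)^2 + M_2(\bar x_{i2} - \bar x_i)^2}
#'   {\{(M_1 - 1) S_{i1}^2 + (M_2 - 1) S_{i2}^2\}/(M - 2)}}
#' which for two groups equals the squared pooled-variance two-sample
#' t-statistic (and the one-way ANOVA F).
#'
#' If the pooled-variance denominator is exactly zero the statistic is
#' defined as 0 when the two group means agree, and otherwise the
#' denominator is replaced by `1e-12` (yielding a very large but finite
#' value); both fallbacks are tallied in [bsm_event_log()].
#'
#' @param dataset An [expression_dataset()].
#' @param gene_index Optional gene index/id vector; default all genes.
#' @return Numeric vector of F-statistics (named by gene id), all >= 0.
#' @export
f_statistic <- function(dataset, gene_index = NULL) {
  .check_dataset(dataset)
  f <- .f_statistics(dataset)
  if (is.null(gene_index)) f else f[.resolve_genes(dataset, gene_index)]
}

.f_statistics <- function(dataset) {
  x <- dataset$values
  ic <- .case_cols(dataset)
  it <- .ctrl_cols(dataset)
  m1 <- length(ic)
  m2 <- length(it)
  m <- m1 + m2
  mu1 <- rowMeans(x[, ic, drop = FALSE])
  mu2 <- rowMeans(x[, it, drop = FALSE])
  mu <- (m1 * mu1 + m2 * mu2) / m
  v1 <- .row_vars(x[, ic, drop = FALSE], mu1)
  v2 <- .row_vars(x[, it, drop = FALSE], mu2)
  num <- m1 * (mu1 - mu)^2 + m2 * (mu2 - mu)^2
  den <- ((m1 - 1) * v1 + (m2 - 1) * v2) / (m - 2)
  f <- numeric(length(num))
  ok <- den > 0
  f[ok] <- num[ok] / den[ok]
  deg <- !ok & num > 1e-20     # zero pooled variance, unequal means
  if (any(deg)) {
    .log_event("f_statistic_epsilon_denominator", sum(deg))
    f[deg] <- num[deg] / 1e-12
  }
  names(f) <- rownames(x)
  f
}

.row_vars <- function(x, mu) {
  n <- ncol(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Pearson redundancy between two genes
#'
#' The MRMR redundancy measure: the Pearson correlation of two genes'
#' expression profiles across all samples, ignoring class labels.  A gene
#' with zero variance has no defined correlation; its redundancy is taken
#' as 0 (with a warning) so that downstream weights stay finite.
#'
#' @param dataset An [expression_dataset()].
#' @param i,j Gene indices or ids.
#' @return Correlation in `[-1, 1]`; symmetric in `(i, j)`.
#' @export
pearson_redundancy <- function(dataset, i, j) {
  .check_dataset(dataset)
  i <- .resolve_genes(dataset, i)
  j <- .resolve_genes(dataset, j)
  xi <- dataset$values[i, ]
  xj <- dataset$values[j, ]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
    .log_event("zero_variance_gene_correlation")
    warning("zero-variance gene; redundancy defined as 0")
    return(0)
  }
  stats::cor(xi, xj)
}

#' MRMR weights for all genes
#'
#' Relevance divided by mean redundancy:
#' \deqn{w_i = F(i) \Big/ \Big\{ \frac{1}{N-1} \sum_{j \ne i} |R(i, j)| \Big\}}
#' with \eqn{F} the two-group F-statistic and \eqn{R} the Pearson
#' correlation.  A mean absolute correlation of exactly 0 is replaced by
#' `1e-12` to keep the weight finite.
#'
#' @param dataset An [expression_dataset()] with at least 2 genes.
#' @param quiet Suppress the zero-variance warning (the event is still
#'   tallied); used by the bootstrap loop where near-degenerate resampled
#'   columns are routine.
#' @return Named numeric vector of nonnegative weights, one per gene.
#' @export
mrmr_weights <- function(dataset, quiet = FALSE) {
  .check_dataset(dataset)
  n <- .n_genes(dataset)
  if (n < 2L) stop("MRMR redundancy is undefined for a single gene")
  f <- .f_statistics(dataset)
  cm <- suppressWarnings(stats::cor(t(dataset$values)))
  bad <- !is.finite(cm)
  if (any(bad)) {
    nbad <- sum(!is.finite(diag(cm)))
    .log_event("zero_variance_gene_correlation", nbad)
    if (!quiet)
      warning(nbad, " zero-variance gene(s); their correlation ",
              "contributions are defined as 0")
    cm[bad] <- 0
  }
  mean_abs <- (rowSums(abs(cm)) - abs(diag(cm))) / (n - 1)
  zero_den <- mean_abs <= 0
  if (any(zero_den)) {
    .log_event("mrmr_epsilon_denominator", sum(zero_den))
    mean_abs[zero_den] <- 1e-12
  }
  f / mean_abs
}

#' Preliminary fold-change / t-test gene filter
#'
#' Screens out genes before the main selection: a gene is retained when its
#' absolute log2 fold change (difference of group means on the log2 scale)
#' is at least `fc_threshold` *and* its Welch two-sample t-test p-value is
#' below `p_threshold`.  Defaults mirror the conventional (1, 0.05)
#' setting.
#'
#' @param dataset An [expression_dataset()] with log2-scale values.
#' @param fc_threshold Minimum absolute log2 fold change (> 0).
#' @param p_threshold Welch t-test p-value cutoff (> 0).
#' @return The reduced [expression_dataset()], sample order preserved.
#' @export
preliminary_filter <- function(dataset, fc_threshold = 1, p_threshold = 0.05) {
  .check_dataset(dataset)
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  x <- dataset$values
  ic <- .case_cols(dataset)
  it <- .ctrl_cols(dataset)
  m1 <- length(ic)
  m2 <- length(it)
  mu1 <- rowMeans(x[, ic, drop = FALSE])
  mu2 <- rowMeans(x[, it, drop = FALSE])
  v1 <- .row_vars(x[, ic, drop = FALSE], mu1)
  v2 <- .row_vars(x[, it, drop = FALSE], mu2)
  se2 <- v1 / m1 + v2 / m2
  tt <- ifelse(se2 > 0, (mu1 - mu2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / m1)^2 / (m1 - 1) + (v2 / m2)^2 / (m2 - 1)),
               m1 + m2 - 2)
  pval <- 2 * stats::pt(-abs(tt), df)
  keep <- abs(mu1 - mu2) >= fc_threshold & pval < p_threshold
  if (!any(keep))
    stop("preliminary filter removed every gene; relax fc_threshold/",
         "p_threshold")
  expression_dataset(x[keep, , drop = FALSE],
                     stats::setNames(dataset$labels, colnames(x)))
}
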