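#' Bootstrap resample of subjects (columns)
#'
#' Draws M samples with replacement from the M columns of the dataset,
#' each drawn column keeping its class label — subjects are treated as the
#' i.i.d. units while within-subject gene-gene correlation is preserved.
#' Draws leaving fewer than 2 subjects in either class are rejected and
#' redrawn (at most 1000 attempts); redraws are tallied in
#' [bsm_event_log()].
#'
#' Resampled columns are renamed `<sample id>.b<draw>` so the result is a
#' valid dataset with unique sample ids.
#'
#' @param dataset An [expression_dataset()].
#' @param seed Optional seed; `NULL` (the default) draws from the current
#'   RNG state, which is what [bsm_select()] relies on.
#' @return An [expression_dataset()] with M columns.
#' @export
bootstrap_resample <- function(dataset, seed = NULL) {
  .check_dataset(dataset)
  if (!is.null(seed)) set.seed(seed)
  m <- .n_samples(dataset)
  for (attempt in seq_len(1000L)) {
    idx <- sample.int(m, m, replace = TRUE)
    lab <- dataset$labels[idx]
    if (sum(lab == 1L) >= 2L && sum(lab == -1L) >= 2L) {
      vals <- dataset$values[, idx, drop = FALSE]
      colnames(vals) <- paste0(colnames(dataset$values)[idx], ".b",
                               seq_len(m))
      return(expression_dataset(vals, lab))
    }
    .log_event("bootstrap_redraw")
  }
  stop("1000 bootstrap draws rejected; class imbalance too extreme")
}

#' Rank scores from gene positions
#'
#' Converts the positions of genes in one ranked list (1 = best) to rank
#' scores \eqn{R_i = (N + 1 - P_i)/N \in [1/N, 1]}: near 1 for top-ranked
#' genes, near 0 for bottom-ranked ones.  Over a full ranking the scores
#' are exactly \eqn{\{1/N, 2/N, \dots, 1\}}, with median approaching 0.5
#' and third quartile 0.75 as N grows.
#'
#' @param positions Integer permutation of `1:N`.
#' @return Numeric vector of rank scores.
#' @export
rank_scores <- function(positions) {
  n <- length(positions)
  if (n < 1L || !all(sort(positions) == seq_len(n)))
    stop("'positions' must be a permutation of 1..N")
  (n + 1 - positions) / n
}

#' Signed-rank statistic of bootstrap rank scores
#'
#' For one gene's rank scores \eqn{R_1, \dots, R_B} over B bootstrap
#' resamples, tests whether the gene sits above the third quartile
#' (Q3 = 0.75) of the rank-score distribution: with
#' \eqn{Z_b = 1\{R_b > Q3\}} and \eqn{r_b} the ascending rank of
#' \eqn{|R_b - Q3|} (ties averaged),
#' \deqn{W = \sum_{b=1}^{B} Z_b r_b, \qquad 0 \le W \le B(B+1)/2.}
#' Large W means the gene lands in the top quartile often and by a wide
#' margin — the one-sided signed-rank evidence that it is consistently
#' highly ranked.
#'
#' @param r_i Numeric vector of B rank scores in `[0, 1]`.
#' @return The statistic W (single numeric).
#' @export
signed_rank_statistic <- function(r_i) {
  if (!length(r_i)) stop("'r_i' must be non-empty")
  if (!is.numeric(r_i) || any(r_i < 0 | r_i > 1))
    stop("rank scores must lie in [0, 1]")
  z <- r_i > 0.75
  r <- rank(abs(r_i - 0.75), ties.method = "average")
  sum(r[z])
}

#' Null mean and variance of the signed-rank statistic
#'
#' Under the null that a gene has probability 1/4 of exceeding Q3 in any
#' bootstrap resample, independently of the magnitude ranks, the statistic
#' of [signed_rank_statistic()] has
#' \deqn{E(W) = B(B+1)/8, \qquad V(W) = B(B+1)(2B+1)/32.}
#'
#' @param B Number of bootstrap resamples (>= 1).
#' @return List with elements `mean` and `variance`.
#' @export
null_moments <- function(B) {
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B))
    stop("'B' must be a single integer >= 1")
  list(mean = B * (B + 1) / 8,
       variance = B * (B + 1) * (2 * B + 1) / 32)
}

#' One-sided p-values for signed-rank statistics
#'
#' Standardizes each W by the closed-form null moments and applies the
#' normal approximation \eqn{Z_i = (W_i - E(W))/\sqrt{V(W)} \to N(0, 1)};
#' the p-value is the upper tail (the alternative is one-sided: the gene's
#' rank score exceeds Q3).
#'
#' @param W Numeric vector of statistics (one per gene).
#' @param B Number of bootstrap resamples the statistics were computed
#'   from; a warning is issued below 30, where the normal approximation
#'   is shaky.
#' @return Numeric vector of p-values in (0, 1), strictly decreasing in W.
#' @export
gene_pvalues <- function(W, B) {
  mom <- null_moments(B)
  if (B < 30)
    warning("normal approximation with B = ", B,
            " bootstrap resamples is unreliable; consider B >= 30")
  if (any(W < 0 | W > B * (B + 1) / 2))
    stop("W outside [0, B(B+1)/2]")
  z <- (W - mom$mean) / sqrt(mom$variance)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Hochberg step-up adjusted p-values
#'
#' Standard Hochberg step-up adjustment controlling the family-wise error
#' rate: with ascending ordered p-values, \eqn{\tilde p_{(N)} = p_{(N)}}
#' and \eqn{\tilde p_{(i)} = \min(\tilde p_{(i+1)}, (N - i + 1) p_{(i)})},
#' capped at 1 and mapped back to the input order.  Computed via
#' [stats::p.adjust()]; a gene is rejected at level alpha exactly when its
#' adjusted p-value is at most alpha.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, element-wise >= `p`.
#' @export
hochberg_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("'p' must be numeric in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' BSM gene selection: bootstrap SVM-MRMR with signed-rank inference
#'
#' The full selection pipeline.  On each of B bootstrap resamples of the
#' subjects, MRMR weights and linear-SVM weights are recomputed, min-max
#' normalized and fused by the quadratic integration score
#' ([quadratic_integration()]); genes are ranked by descending score
#' (ties broken by gene id) and the position of each gene recorded.  The
#' per-gene positions become rank scores ([rank_scores()]), the one-sided
#' signed-rank statistic against Q3 = 0.75 is computed over the B
#' resamples ([signed_rank_statistic()]), normal-approximation p-values
#' follow ([gene_pvalues()]), and Hochberg adjustment
#' ([hochberg_adjust()]) yields the selection at level `alpha`.
#'
#' @param dataset An [expression_dataset()].
#' @param B Number of bootstrap resamples; default 200, a conventional
#'   choice for bootstrap estimation.
#' @param beta Integration tradeoff in (0, 1), or `"auto"` to pick it by
#'   cross-validated accuracy ([select_beta()]) on the full data before
#'   the bootstrap loop.
#' @param alpha Significance level for the adjusted p-values.
#' @param C Soft-margin cost of the ranking SVM.
#' @param seed Optional seed making the whole run reproducible.
#' @param beta_grid,n_top,folds Passed to [select_beta()] when
#'   `beta = "auto"`.
#' @return A `gene_result_table` (data frame, one row per gene in the
#'   input order) with columns `gene_id`, `mrmr_weight`, `svm_weight`,
#'   `sd_score` (all computed on the full data), `w_stat`, `z_score`,
#'   `p_value`, `adj_p_value`, `selected`.  Attributes: `B`, `beta`,
#'   `alpha`, `C`, `seed`, `events` (fallback tallies from this run),
#'   and `rank_scores` (the B x N matrix of \eqn{R_{ib}}).
#' @export
bsm_select <- function(dataset, B = 200L, beta = 0.5, alpha = 0.05, C = 1,
                       seed = NULL, beta_grid = seq(0.05, 0.95, by = 0.05),
                       n_top = 50L, folds = 5L) {
  .check_dataset(dataset)
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  events_before <- bsm_event_log()

  if (identical(beta, "auto"))
    beta <- as.numeric(select_beta(dataset, grid = beta_grid, n_top = n_top,
                                   folds = folds, seed = NULL, C = C))

  n <- .n_genes(dataset)
  ids <- .gene_ids(dataset)

  # full-data weights and score, reported alongside the inference
  w_full <- mrmr_weights(dataset, quiet = TRUE)
  k_full <- svm_weights(train_linear_svm(dataset, C = C))
  sd_full <- .sd_score(w_full, k_full, beta)

  positions <- matrix(NA_integer_, nrow = B, ncol = n,
                      dimnames = list(NULL, ids))
  for (b in seq_len(B)) {
    ds_b <- bootstrap_resample(dataset)
    w_b <- mrmr_weights(ds_b, quiet = TRUE)
    k_b <- svm_weights(train_linear_svm(ds_b, C = C))
    sd_b <- .sd_score(w_b, k_b, beta)
    ord <- order(-sd_b, ids)
    positions[b, ord] <- seq_len(n)
  }
  rscores <- (n + 1 - positions) / n

  W <- vapply(seq_len(n), function(i) signed_rank_statistic(rscores[, i]),
              numeric(1))
  mom <- null_moments(B)
  z <- (W - mom$mean) / sqrt(mom$variance)
  p <- if (B >= 30) gene_pvalues(W, B) else
    suppressWarnings(gene_pvalues(W, B))
  padj <- hochberg_adjust(p)

  res <- data.frame(
    gene_id = ids,
    mrmr_weight = unname(w_full),
    svm_weight = unname(k_full),
    sd_score = unname(sd_full),
    w_stat = W,
    z_score = z,
    p_value = p,
    adj_p_value = padj,
    selected = padj <= alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  events_after <- bsm_event_log()
  delta_events <- .diff_events(events_before, events_after)
  structure(res,
            class = c("gene_result_table", "data.frame"),
            B = B, beta = beta, alpha = alpha, C = C, seed = seed,
            events = delta_events, rank_scores = rscores)
}

.diff_events <- function(before, after) {
  nms <- names(after)
  out <- vapply(nms, function(nm) {
    after[[nm]] - (if (nm %in% names(before)) before[[nm]] else 0L)
  }, integer(1))
  out[out > 0L]
}

#' @export
print.gene_result_table <- function(x, ...) {
  cat("BSM gene result table: ", nrow(x), " genes, ",
      sum(x$selected), " selected (B = ", attr(x, "B"),
      ", beta = ", signif(attr(x, "beta"), 3),
      ", alpha = ", attr(x, "alpha"), ")\n", sep = "")
  ord <- order(x$adj_p_value, x$gene_id)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], 10L))
  if (nrow(x) > 10L)
    cat("... (", nrow(x) - 10L, " more genes; ordered by adjusted p)\n",
        sep = "")
  invisible(x)
}
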