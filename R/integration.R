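#' Min-max normalization of a weight vector
#'
#' Rescales weights linearly onto `[0, 1]`:
#' \deqn{w_i^{norm} = (w_i - \min_j w_j) / (\max_j w_j - \min_j w_j).}
#' A constant vector (where the formula is 0/0) maps to all zeros — a
#' constant ranking carries no information.
#'
#' @param weights Finite numeric vector (names preserved).
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(weights) {
  if (!is.numeric(weights) || !all(is.finite(weights)))
    stop("'weights' must be finite numeric")
  .minmax(weights)
}

.minmax <- function(w) {
  rng <- range(w)
  if (rng[1L] == rng[2L]) {
    w[] <- 0
    return(w)
  }
  (w - rng[1L]) / (rng[2L] - rng[1L])
}

#' Linear combination of MRMR and SVM weights
#'
#' The earlier linear fusion rule \eqn{SL_i = \delta w_i + (1-\delta)|k_i|},
#' retained for comparison with the quadratic integration score.  Its
#' ordering can swing with \eqn{\delta} when the two weight vectors are
#' negatively correlated, which is what motivates the rank-weighted score
#' of [quadratic_integration()].
#'
#' @param w,k Numeric weight vectors of equal length (MRMR weights and
#'   absolute SVM weights).
#' @param delta Tradeoff in `[0, 1]`; 1 = pure MRMR, 0 = pure SVM.
#' @return Numeric vector of scores.
#' @export
sl_score <- function(w, k, delta) {
  if (length(w) != length(k)) stop("'w' and 'k' must have equal length")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1)
    stop("'delta' must be a single value in [0, 1]")
  delta * w + (1 - delta) * k
}

#' Quadratic integration of normalized MRMR and SVM weights
#'
#' Fuses the two normalized weight vectors through their ascending ranks
#' \eqn{\gamma_i^{MR}, \gamma_i^{SV}} (1 = smallest weight, ties averaged):
#' \deqn{SD_i = \frac{\beta\,\gamma_i^{MR} w_i^{norm} +
#'   (1-\beta)\,\gamma_i^{SV} |k_i|^{norm}}
#'   {\beta\,\gamma_i^{MR} + (1-\beta)\,\gamma_i^{SV}}.}
#' Each gene's score is a rank-weighted mean of its two normalized
#' weights, so the better-ranked source dominates gene by gene; ranks are
#' at least 1, hence the denominator is always positive and
#' \eqn{SD_i \in [0, 1]}.
#'
#' @param w_norm,k_norm Min-max normalized weight vectors (see
#'   [minmax_normalize()]) of equal length.
#' @param beta Tradeoff in the open interval (0, 1); larger values favour
#'   the MRMR side.
#' @return An object of class `integration_score`: list with `score`
#'   (named SD values), `rank_mrmr`, `rank_svm`, `beta`, and the inputs.
#' @export
quadratic_integration <- function(w_norm, k_norm, beta) {
  if (length(w_norm) != length(k_norm))
    stop("'w_norm' and 'k_norm' must have equal length")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must be a single value in (0, 1)")
  if (!all(is.finite(w_norm)) || !all(is.finite(k_norm)))
    stop("weights must be finite")
  g_mr <- rank(w_norm, ties.method = "average")
  g_sv <- rank(k_norm, ties.method = "average")
  sd_i <- (beta * g_mr * w_norm + (1 - beta) * g_sv * k_norm) /
    (beta * g_mr + (1 - beta) * g_sv)
  structure(list(score = sd_i, rank_mrmr = g_mr, rank_svm = g_sv,
                 w_norm = w_norm, k_norm = k_norm, beta = beta),
            class = "integration_score")
}

#' @export
print.integration_score <- function(x, ...) {
  cat("integration_score: ", length(x$score), " genes, beta = ",
      x$beta, "\n", sep = "")
  invisible(x)
}

# fast path used inside the bootstrap loop: raw weights in, SD out
.sd_score <- function(w, k, beta) {
  wn <- .minmax(w)
  kn <- .minmax(k)
  g_mr <- rank(wn, ties.method = "average")
  g_sv <- rank(kn, ties.method = "average")
  (beta * g_mr * wn + (1 - beta) * g_sv * kn) /
    (beta * g_mr + (1 - beta) * g_sv)
}

#' Choose the integration tradeoff by cross-validated accuracy
#'
#' For each candidate `beta`, scores all genes on the full data, takes the
#' `n_top` genes with the highest SD score, and estimates classification
#' accuracy of a linear SVM on those genes by stratified k-fold
#' cross-validation (one seeded fold assignment shared across candidates).
#' Returns the candidate with the highest mean accuracy; ties go to the
#' smallest `beta` (favouring redundancy control).
#'
#' @param dataset An [expression_dataset()].
#' @param grid Candidate values, all in (0, 1).
#' @param n_top Number of top-scoring genes fed to the classifier.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Optional seed for the fold assignment.
#' @param C Cost of the cross-validation SVM classifier.
#' @param weight_fun Function `dataset -> list(mrmr =, svm =)` producing
#'   the two raw weight vectors; defaults to [mrmr_weights()] and
#'   [svm_weights()] of [train_linear_svm()].  Injectable for testing.
#' @return The selected beta (single numeric), with the per-candidate mean
#'   accuracies attached as attribute `"accuracy"`.
#' @export
select_beta <- function(dataset, grid = seq(0.05, 0.95, by = 0.05),
                        n_top = 50L, folds = 5L, seed = NULL, C = 1,
                        weight_fun = NULL) {
  .check_dataset(dataset)
  if (!length(grid) || any(grid <= 0 | grid >= 1))
    stop("'grid' must be a non-empty set of values in (0, 1)")
  if (folds < 2L) stop("'folds' must be at least 2")
  n_top <- min(as.integer(n_top), .n_genes(dataset))
  if (!is.null(seed)) set.seed(seed)

  if (is.null(weight_fun))
    weight_fun <- function(ds)
      list(mrmr = mrmr_weights(ds, quiet = TRUE),
           svm = svm_weights(train_linear_svm(ds, C = C)))
  wts <- weight_fun(dataset)
  fold_ids <- .stratified_folds(dataset$labels, folds)

  grid <- sort(unique(grid))
  acc <- vapply(grid, function(b) {
    sd_i <- .sd_score(wts$mrmr, wts$svm, b)
    top <- order(-sd_i, .gene_ids(dataset))[seq_len(n_top)]
    .cv_accuracy(dataset$values[top, , drop = FALSE], dataset$labels,
                 fold_ids, kernel = "linear", C = C)
  }, numeric(1))
  best <- grid[which.max(acc)]          # which.max takes the first maximum;
  attr(best, "accuracy") <- stats::setNames(acc, grid)  # grid is ascending
  best
}
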