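#' Train a linear two-class SVM on genes as features
#'
#' Fits a soft-margin linear support-vector machine separating case from
#' control samples, with the dual solved by libsvm (via \pkg{e1071}).  The
#' primal weight of gene i is recovered from the dual solution as
#' \deqn{k_i = \sum_m \varphi_m y_m x_{im}, \qquad \sum_m \varphi_m y_m = 0,
#'   \; 0 \le \varphi_m \le C,}
#' and `|k_i|` is the gene-ranking metric (see [svm_weights()]).  With a
#' large `C` on separable data this recovers the hard-margin solution.
#'
#' libsvm orients its decision function toward whichever class it sees
#' first; the returned model is re-oriented so that positive decision
#' values always mean the case (+1) class.
#'
#' @param dataset An [expression_dataset()].
#' @param C Soft-margin cost (> 0); default 1.
#' @param scale Standardize features before fitting; default `FALSE`
#'   (expression values are assumed already on a common log2 scale).
#' @param tolerance Termination tolerance of the dual solver; tighten
#'   (e.g. `1e-8`) when near-exact hard-margin solutions are needed.
#' @return An object of class `svm_model`: list with elements `k` (named
#'   primal weights), `b` (bias), `phi` (dual coefficients, one per
#'   sample, zero off the support), `labels`, `C`, and the underlying
#'   \pkg{e1071} `fit`.
#' @export
train_linear_svm <- function(dataset, C = 1, scale = FALSE,
                             tolerance = 0.001) {
  .check_dataset(dataset)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("'C' must be a single positive number")
  y <- dataset$labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- t(dataset$values)                      # samples x genes
  if (!all(is.finite(X))) stop("non-finite expression values")
  fit <- e1071::svm(X, factor(y, levels = c(-1, 1)), type = "C-classification",
                    kernel = "linear", cost = C, scale = scale,
                    tolerance = tolerance)
  k <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm coefs are phi_m * y_m in its internal orientation; re-orient so
  # +1 is the case class (the sign of a support vector's coef must match
  # its label)
  if (sign(fit$coefs[1L]) != y[fit$index[1L]]) {
    k <- -k
    b <- -b
  }
  phi <- numeric(length(y))
  phi[fit$index] <- abs(fit$coefs)
  names(k) <- .gene_ids(dataset)
  structure(list(k = k, b = b, phi = phi, labels = y, C = C, fit = fit),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat("linear svm_model: ", length(x$k), " genes, ",
      sum(x$phi > 0), " support vectors, C = ", x$C, "\n", sep = "")
  invisible(x)
}

#' Per-gene SVM ranking weights
#'
#' Absolute primal weights `|k_i|` of a fitted linear SVM — the wrapper
#' half of the BSM score.
#'
#' @param model An `svm_model` from [train_linear_svm()].
#' @return Named nonnegative numeric vector, one entry per gene.
#' @export
svm_weights <- function(model) {
  if (!inherits(model, "svm_model"))
    stop("expected an 'svm_model' (see train_linear_svm())")
  abs(model$k)
}
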