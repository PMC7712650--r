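# Shared cross-validation machinery (stratified folds + pooled accuracy).
# Fold assignment draws from the caller's RNG state, so callers seed once.

.stratified_folds <- function(y, k) {
  k <- as.integer(k)
  ids <- integer(length(y))
  for (cls in c(1L, -1L)) {
    idx <- which(y == cls)
    ids[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k))
    if (length(unique(y[ids == f])) < 2L)
      stop("cross-validation fold ", f, " lacks both classes; ",
           "use fewer folds")
  ids
}

# X is genes x samples; returns the pooled fraction of correctly
# classified held-out samples.  `classifier`, if given, is a function
# (train_x samples-x-genes, train_y) -> function(test_x) -> labels,
# replacing the SVM (used for baseline stubs in tests).
.cv_accuracy <- function(X, y, fold_ids, kernel = "linear", C = 1,
                         classifier = NULL) {
  Xt <- t(X)
  correct <- 0L
  for (f in sort(unique(fold_ids))) {
    test <- fold_ids == f
    if (is.null(classifier)) {
      fit <- e1071::svm(Xt[!test, , drop = FALSE],
                        factor(y[!test], levels = c(-1, 1)),
                        type = "C-classification", kernel = kernel,
                        cost = C, scale = FALSE)
      pred <- as.integer(as.character(
        stats::predict(fit, Xt[test, , drop = FALSE])))
    } else {
      model <- classifier(Xt[!test, , drop = FALSE], y[!test])
      pred <- model(Xt[test, , drop = FALSE])
    }
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}
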