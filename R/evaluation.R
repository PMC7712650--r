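#' Sliding-window configuration
#'
#' Windows of `S` consecutive ranked genes slid by `L` across a ranked set
#' of size `n` give `K = floor((n - S)/L)` windows; window k covers ranked
#' positions `(k-1)L + 1` to `(k-1)L + S`.
#'
#' @param n Size of the ranked gene set.
#' @param S Window size (number of ranked genes per window), `S <= n`.
#' @param L Sliding length (>= 1).
#' @return List of class `window_config` with elements `n`, `S`, `L`, `K`.
#' @export
window_config <- function(n, S, L) {
  if (S > n) stop("window size S must not exceed n")
  if (L < 1L) stop("sliding length L must be at least 1")
  K <- floor((n - S) / L)
  if (K < 1L) stop("configuration yields no complete window (K < 1)")
  structure(list(n = as.integer(n), S = as.integer(S), L = as.integer(L),
                 K = as.integer(K)),
            class = "window_config")
}

#' Classification accuracy over sliding windows of ranked genes
#'
#' Evaluates how informative a gene ranking is: window k holds the ranked
#' genes at positions `(k-1)L + 1 ... (k-1)L + S`; for each window an SVM
#' classifier with the requested kernel is assessed by seeded stratified
#' k-fold cross-validation, and `CA_k` is the pooled fraction of correctly
#' classified held-out samples.  Reported are the per-window accuracies,
#' their mean \eqn{\mu CA = \sum_k CA_k / K} and the population-form
#' standard error \eqn{SE = \sqrt{\sum_k (CA_k - \mu CA)^2 / K}}.
#'
#' A good ranking keeps accuracy high in the first windows and decaying
#' slowly — high mean CA with low SE.
#'
#' @param dataset An [expression_dataset()].
#' @param ranked_genes Character vector of gene ids, best first; all must
#'   be present in the dataset and their number must equal `config$n`.
#' @param config A [window_config()].
#' @param kernel SVM kernel: `"linear"`, `"radial"`, `"polynomial"` or
#'   `"sigmoid"` (kernel hyperparameters at \pkg{e1071} defaults).
#' @param folds Cross-validation folds.
#' @param seed Optional seed for the fold assignment (shared across
#'   windows).
#' @param classifier Optional classifier stub replacing the SVM; a
#'   function `(train_x, train_y) -> function(test_x) -> labels`.
#' @return List of class `ca_summary`: `ca` (length-K vector), `mean_ca`,
#'   `se_ca`, and the configuration.
#' @export
sliding_window_accuracy <- function(dataset, ranked_genes, config,
                                    kernel = c("linear", "radial",
                                               "polynomial", "sigmoid"),
                                    folds = 5L, seed = NULL,
                                    classifier = NULL) {
  .check_dataset(dataset)
  kernel <- match.arg(kernel)
  if (!inherits(config, "window_config"))
    stop("'config' must be a window_config()")
  if (length(ranked_genes) != config$n)
    stop("length of 'ranked_genes' (", length(ranked_genes),
         ") does not match config$n (", config$n, ")")
  missing <- setdiff(ranked_genes, .gene_ids(dataset))
  if (length(missing))
    stop("ranked gene(s) not in dataset: ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fold_ids <- .stratified_folds(dataset$labels, folds)

  ca <- vapply(seq_len(config$K), function(k) {
    win <- ranked_genes[(k - 1L) * config$L + seq_len(config$S)]
    .cv_accuracy(dataset$values[win, , drop = FALSE], dataset$labels,
                 fold_ids, kernel = kernel, classifier = classifier)
  }, numeric(1))
  mean_ca <- mean(ca)
  se_ca <- sqrt(mean((ca - mean_ca)^2))
  structure(list(ca = ca, mean_ca = mean_ca, se_ca = se_ca,
                 config = config, kernel = kernel, folds = folds),
            class = "ca_summary")
}

#' @export
print.ca_summary <- function(x, ...) {
  cat("sliding-window accuracy (", x$kernel, " kernel, K = ",
      x$config$K, " windows of ", x$config$S, "):\n", sep = "")
  cat("  mean CA = ", round(x$mean_ca, 4),
      ", SE = ", round(x$se_ca, 4), "\n", sep = "")
  invisible(x)
}

#' Count genes fully contained in QTL intervals
#'
#' A gene counts when its genomic span lies entirely within at least one
#' QTL on the same chromosome (gene start >= QTL start and gene stop <=
#' QTL stop; 1-based inclusive coordinates).  Each gene counts at most
#' once however many QTLs contain it; the raw gene-QTL containment pair
#' count is attached as attribute `"n_pairs"`.
#'
#' @param gene_set Character vector of gene ids.
#' @param gene_coords Named [GenomicRanges::GRanges] of gene spans; genes
#'   in `gene_set` without coordinates are excluded with a warning.
#' @param qtls [GenomicRanges::GRanges] of QTL intervals.
#' @return Integer count (Qstat).
#' @export
qtl_qstat <- function(gene_set, gene_coords, qtls) {
  if (is.null(names(gene_coords)))
    stop("'gene_coords' must be named by gene id")
  missing <- setdiff(gene_set, names(gene_coords))
  if (length(missing))
    warning("no coordinates for ", length(missing),
            " gene(s); excluded: ", paste(missing, collapse = ", "))
  keep <- intersect(gene_set, names(gene_coords))
  if (!length(keep)) {
    out <- 0L
    attr(out, "n_pairs") <- 0L
    return(out)
  }
  hits <- GenomicRanges::findOverlaps(gene_coords[keep], qtls,
                                      type = "within")
  out <- length(unique(S4Vectors::queryHits(hits)))
  attr(out, "n_pairs") <- length(hits)
  out
}

#' Hypergeometric enrichment p-value for QTL containment
#'
#' Upper-tail hypergeometric probability of observing at least `v` of the
#' `n` selected genes inside QTLs, when `V` of the `N` genes genome-wide
#' are inside QTLs:
#' \deqn{p = \sum_{u = v}^{\min(n, V)} \binom{V}{u}\binom{N-V}{n-u} \Big/
#'   \binom{N}{n}.}
#'
#' @param v Observed count of selected genes contained in >= 1 QTL.
#' @param N Total number of genes.
#' @param V Genome-wide count of genes contained in >= 1 QTL.
#' @param n Size of the selected gene set.
#' @return The enrichment p-value in (0, 1].
#' @export
qtl_enrichment_pvalue <- function(v, N, V, n) {
  if (v < 0 || V < 0 || n < 0 || N < 1)
    stop("counts must be nonnegative (N >= 1)")
  if (v > n) stop("inconsistent counts: v > n")
  if (v > V) stop("inconsistent counts: v > V")
  if (V > N) stop("inconsistent counts: V > N")
  if (n > N) stop("inconsistent counts: n > N")
  stats::phyper(v - 1, V, N - V, n, lower.tail = FALSE)
}

#' GO Jaccard distance between two genes
#'
#' \eqn{d_{ij} = 1 - |GO_i \cap GO_j| / |GO_i \cup GO_j|}: 0 for identical
#' term sets, 1 for disjoint ones.  Undefined when both sets are empty
#' (error); [go_average_distance()] skips such pairs.
#'
#' @param terms_i,terms_j Character vectors of term ids.
#' @return Distance in `[0, 1]`.
#' @export
go_distance <- function(terms_i, terms_j) {
  terms_i <- unique(terms_i)
  terms_j <- unique(terms_j)
  if (!length(terms_i) && !length(terms_j))
    stop("distance undefined when both term sets are empty")
  1 - length(intersect(terms_i, terms_j)) /
    length(union(terms_i, terms_j))
}

#' Average GO distance of a gene set
#'
#' Mean pairwise Jaccard distance
#' \eqn{D^{avg} = \frac{2}{n(n-1)} \sum_{i < j} d_{ij}}
#' over the annotated genes of the set; a lower value means a more
#' functionally coherent selection.  Pairs involving a gene with an empty
#' term set are skipped and the divisor is the number of pairs actually
#' used (reported alongside the skip count).
#'
#' @param gene_set Character vector of gene ids (n >= 2).
#' @param annotations An [annotation_map()].
#' @return List of class `go_summary`: `average`, `distances` (named
#'   vector over used pairs), `n_pairs_used`, `n_unannotated`.
#' @export
go_average_distance <- function(gene_set, annotations) {
  if (length(gene_set) < 2L) stop("need at least 2 genes")
  if (!inherits(annotations, "annotation_map"))
    stop("expected an 'annotation_map'")
  terms <- lapply(gene_set, go_terms, map = annotations)
  names(terms) <- gene_set
  annotated <- gene_set[lengths(terms) > 0L]
  if (length(annotated) < 2L)
    stop("fewer than 2 genes in the set carry annotations")
  pairs <- utils::combn(annotated, 2L)
  d <- apply(pairs, 2L, function(p) go_distance(terms[[p[1L]]],
                                                terms[[p[2L]]]))
  names(d) <- paste(pairs[1L, ], pairs[2L, ], sep = ":")
  structure(list(average = mean(d), distances = d,
                 n_pairs_used = length(d),
                 n_unannotated = length(gene_set) - length(annotated)),
            class = "go_summary")
}

#' @export
print.go_summary <- function(x, ...) {
  cat("GO distance summary: average = ", round(x$average, 4), " over ",
      x$n_pairs_used, " pairs (", x$n_unannotated,
      " unannotated gene(s) skipped)\n", sep = "")
  invisible(x)
}
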