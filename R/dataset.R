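#' Construct a two-class expression dataset
#'
#' Bundles a genes x samples matrix of (log2-scale) expression values with
#' case/control sample labels into a validated object used by every other
#' function in the package.  Rows are genes, columns are samples; labels are
#' coded `+1` (case) and `-1` (control).
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty `rownames` (gene ids) and `colnames` (sample ids).
#'   Values must be finite; missing values are rejected, not imputed.
#' @param labels Vector of length `ncol(values)` with entries in
#'   `{+1, -1}`.  If named, names are matched against the sample ids (order
#'   then does not matter); if unnamed, positional order is assumed.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix) and `labels` (integer vector aligned with the
#'   matrix columns).
#'
#' @details At least 2 genes, 4 samples and 2 samples per class are
#'   required — group variances with divisor (group size - 1) are undefined
#'   below that.
#'
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(x, c(1, 1, -1, -1))
#' ds
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (anyNA(values) || !all(is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  if (!is.null(names(labels))) {
    missing_lab <- setdiff(sample_ids, names(labels))
    extra_lab <- setdiff(names(labels), sample_ids)
    if (length(missing_lab))
      stop("no label for sample(s): ", paste(missing_lab, collapse = ", "))
    if (length(extra_lab))
      stop("label(s) for unknown sample(s): ",
           paste(extra_lab, collapse = ", "))
    labels <- labels[sample_ids]
  }
  if (length(labels) != ncol(values))
    stop("'labels' must have one entry per sample")
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be coded +1 (case) / -1 (control)")

  n_case <- sum(labels == 1L)
  n_ctrl <- sum(labels == -1L)
  if (nrow(values) < 2L) stop("at least 2 genes are required")
  if (ncol(values) < 4L) stop("at least 4 samples are required")
  if (n_case < 2L || n_ctrl < 2L)
    stop("each class needs at least 2 samples (got ",
         n_case, " case, ", n_ctrl, " control)")

  structure(list(values = values, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (", sum(x$labels == 1L), " case / ",
      sum(x$labels == -1L), " control)\n", sep = "")
  invisible(x)
}

# internal accessors
.n_genes <- function(ds) nrow(ds$values)
.n_samples <- function(ds) ncol(ds$values)
.gene_ids <- function(ds) rownames(ds$values)
.sample_ids <- function(ds) colnames(ds$values)
.case_cols <- function(ds) which(ds$labels == 1L)
.ctrl_cols <- function(ds) which(ds$labels == -1L)

.check_dataset <- function(ds) {
  if (!inherits(ds, "expression_dataset"))
    stop("expected an 'expression_dataset' (see expression_dataset())")
  invisible(ds)
}

#' Per-gene group summary statistics
#'
#' Case mean, control mean, overall mean and the two group variances
#' (sample variances, divisor group size - 1) for every gene.
#'
#' @param dataset An [expression_dataset()].
#' @return A data frame with one row per gene and columns `gene_id`,
#'   `mean_case`, `mean_control`, `mean_all`, `var_case`, `var_control`.
#' @seealso [gene_covariance()] for the pairwise covariance.
#' @export
group_summary <- function(dataset) {
  .check_dataset(dataset)
  x <- dataset$values
  ic <- .case_cols(dataset)
  it <- .ctrl_cols(dataset)
  data.frame(
    gene_id = rownames(x),
    mean_case = rowMeans(x[, ic, drop = FALSE]),
    mean_control = rowMeans(x[, it, drop = FALSE]),
    mean_all = rowMeans(x),
    var_case = apply(x[, ic, drop = FALSE], 1L, stats::var),
    var_control = apply(x[, it, drop = FALSE], 1L, stats::var),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Covariance between two genes across all samples
#'
#' @param dataset An [expression_dataset()].
#' @param i,j Gene indices or gene ids.
#' @return The sample covariance (divisor M - 1) between the two genes'
#'   expression values, ignoring class labels.
#' @export
gene_covariance <- function(dataset, i, j) {
  .check_dataset(dataset)
  stats::cov(dataset$values[i, ], dataset$values[j, ])
}

.resolve_genes <- function(dataset, genes) {
  if (is.character(genes)) {
    idx <- match(genes, .gene_ids(dataset))
    if (anyNA(idx))
      stop("unknown gene id(s): ", paste(genes[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(genes)
    if (any(idx < 1L | idx > .n_genes(dataset)))
      stop("gene index out of range")
    idx
  }
}
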