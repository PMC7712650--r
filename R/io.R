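#' Read an expression matrix and its sample labels
#'
#' Reads a tab-separated expression matrix (first row sample ids, first
#' column gene ids, numeric body) together with a two-column tab-separated
#' label file (sample id, label).  Labels are matched to matrix columns by
#' sample id — never by file order — so a reordered label file yields the
#' same dataset.
#'
#' Accepted label tokens are `1`/`+1`/`-1` or (case-insensitively)
#' `case`/`control`, mapped to `+1`/`-1`.
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param labels_path Path to the TSV label file (no header).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)

  tab <- tryCatch(
    utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("duplicate 'row.names'", conditionMessage(e)))
        stop("duplicated gene id(s) in ", matrix_path, call. = FALSE)
      stop(e)
    })

  # two layouts: a labelled corner cell gives a gene-id column; a missing
  # corner cell makes read.delim move gene ids into rownames
  if (ncol(tab) >= 1L && !is.numeric(tab[[1L]])) {
    gene_ids <- as.character(tab[[1L]])
    body <- tab[-1L]
  } else {
    gene_ids <- rownames(tab)
    body <- tab
  }
  sample_ids <- colnames(body)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id(s) in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s) in ", matrix_path)

  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = ncol(body),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      if (!is.na(bad))
        stop("non-numeric value '", col[bad], "' at gene '", gene_ids[bad],
             "', sample '", sample_ids[j], "' in ", matrix_path)
      col <- num
    }
    if (anyNA(col))
      stop("missing value at gene '", gene_ids[which(is.na(col))[1L]],
           "', sample '", sample_ids[j], "' in ", matrix_path)
    vals[, j] <- col
  }

  lab <- utils::read.delim(labels_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L)
    stop("labels file must have two tab-separated columns (sample id, label)")
  lab_ids <- as.character(lab[[1L]])
  if (anyDuplicated(lab_ids))
    stop("duplicated sample id(s) in ", labels_path)
  labels <- .parse_labels(as.character(lab[[2L]]), labels_path)
  names(labels) <- lab_ids

  missing_lab <- setdiff(sample_ids, lab_ids)
  extra_lab <- setdiff(lab_ids, sample_ids)
  if (length(missing_lab))
    stop("sample(s) in matrix but not in labels file: ",
         paste(missing_lab, collapse = ", "))
  if (length(extra_lab))
    stop("sample(s) in labels file but not in matrix: ",
         paste(extra_lab, collapse = ", "))

  expression_dataset(vals, labels)
}

.parse_labels <- function(tokens, path) {
  low <- tolower(trimws(tokens))
  out <- integer(length(low))
  out[low %in% c("1", "+1", "case")] <- 1L
  out[low %in% c("-1", "control")] <- -1L
  bad <- which(out == 0L)
  if (length(bad))
    stop("unparseable label '", tokens[bad[1L]], "' in ", path,
         " (expected 1/-1 or case/control)")
  out
}

#' Read genomic intervals (genes or QTLs)
#'
#' Reads a four-column tab-separated interval file (chromosome, start, stop,
#' id) into a `GRanges`.  All intervals are held internally in 1-based
#' inclusive coordinates; the `bed0` dialect converts BED's 0-based
#' half-open `[s, e)` to `[s + 1, e]` on input.
#'
#' @param path Path to the interval file (no header).
#' @param dialect `"bed0"` for BED-style 0-based half-open coordinates,
#'   `"inclusive1"` for 1-based inclusive coordinates taken as-is.
#' @return A [GenomicRanges::GRanges] named by interval id.
#' @export
read_intervals <- function(path, dialect = c("bed0", "inclusive1")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interval file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("interval file needs 4 columns (chromosome, start, stop, id): ",
         path)
  start <- .parse_coord(tab[[2L]], path)
  stop_ <- .parse_coord(tab[[3L]], path)
  if (dialect == "bed0") start <- start + 1L
  if (any(start < 1L))
    stop("interval start below 1 after conversion in ", path)
  if (any(stop_ < start)) {
    bad <- which(stop_ < start)[1L]
    stop("interval '", tab[[4L]][bad], "' has stop < start in ", path)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(tab[[1L]]),
    ranges = IRanges::IRanges(start = start, end = stop_)
  )
  names(gr) <- as.character(tab[[4L]])
  gr
}

.parse_coord <- function(x, path) {
  num <- suppressWarnings(as.numeric(x))
  if (anyNA(num))
    stop("non-numeric coordinate '", x[which(is.na(num))[1L]], "' in ", path)
  if (any(num != round(num)))
    stop("non-integer coordinate '", x[which(num != round(num))[1L]],
         "' in ", path)
  as.integer(num)
}

#' Construct a gene -> GO-term annotation map
#'
#' @param mapping Named list; each element is a character vector of term ids
#'   annotating that gene.  Duplicate terms are collapsed.
#' @param category Optional GO category label (`"MF"`, `"BP"` or `"CC"`).
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(mapping, category = NA_character_) {
  if (!is.list(mapping))
    stop("'mapping' must be a named list of term-id vectors")
  if (length(mapping) && is.null(names(mapping)))
    stop("'mapping' must be named by gene id")
  mapping <- lapply(mapping, function(v) sort(unique(as.character(v))))
  if (!is.na(category) && !category %in% c("MF", "BP", "CC"))
    stop("'category' must be one of MF, BP, CC")
  structure(list(mapping = mapping, category = category),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map: ", length(x$mapping), " genes",
      if (!is.na(x$category)) paste0(" [", x$category, "]"), "\n", sep = "")
  invisible(x)
}

#' Term set of one gene
#'
#' @param map An [annotation_map()].
#' @param gene Gene id; genes absent from the map yield the empty set.
#' @return Character vector of term ids (possibly empty).
#' @export
go_terms <- function(map, gene) {
  if (!inherits(map, "annotation_map")) stop("expected an 'annotation_map'")
  terms <- map$mapping[[gene]]
  if (is.null(terms)) character(0) else terms
}

#' Read gene -> GO-term annotations
#'
#' Reads a two- or three-column tab-separated file (gene id, term id, and
#' optionally a GO category).  Duplicate (gene, term) pairs collapse to one;
#' genes not present in the file map to the empty term set on lookup.
#'
#' @param path Path to the annotation file (no header).
#' @param category If the file carries a category column, keep only rows of
#'   this category (`NULL` keeps all rows).
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, category = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("annotation file is empty: ", path)
    return(annotation_map(stats::setNames(list(), character(0)),
                          category = if (is.null(category)) NA_character_
                                     else category))
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("annotation file needs at least 2 columns (gene id, term id): ",
         path)
  if (!is.null(category)) {
    if (ncol(tab) < 3L)
      stop("category filter requested but ", path, " has no category column")
    tab <- tab[tab[[3L]] == category, , drop = FALSE]
  }
  mapping <- split(as.character(tab[[2L]]), as.character(tab[[1L]]))
  annotation_map(mapping,
                 category = if (is.null(category)) NA_character_
                            else category)
}

#' Write an expression dataset to TSV files
#'
#' Writes the matrix (header row of sample ids, first column `gene_id`)
#' and the two-column label file in the formats [read_expression()]
#' accepts.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly, `dataset`.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  .check_dataset(dataset)
  tab <- data.frame(gene_id = rownames(dataset$values),
                    dataset$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(dataset$values),
               label = dataset$labels),
    labels_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dataset)
}

#' Write genomic intervals as 1-based inclusive TSV
#'
#' Four tab-separated columns (chromosome, start, stop, id), readable
#' back with `read_intervals(path, dialect = "inclusive1")`.
#'
#' @param gr A named [GenomicRanges::GRanges].
#' @param path Output path.
#' @return Invisibly, `gr`.
#' @export
write_intervals <- function(gr, path) {
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               stop = GenomicRanges::end(gr),
               id = names(gr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(gr)
}

#' Write a gene -> term annotation map as TSV
#'
#' Two columns (gene id, term id), one row per pair; a third category
#' column is added when the map carries one.
#'
#' @param map An [annotation_map()].
#' @param path Output path.
#' @return Invisibly, `map`.
#' @export
write_annotations <- function(map, path) {
  if (!inherits(map, "annotation_map")) stop("expected an 'annotation_map'")
  gene <- rep(names(map$mapping), lengths(map$mapping))
  term <- unlist(map$mapping, use.names = FALSE)
  tab <- data.frame(gene = gene, term = term, stringsAsFactors = FALSE)
  if (!is.na(map$category)) tab$category <- map$category
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(map)
}

#' Write a gene result table
#'
#' Writes the per-gene output of [bsm_select()] as a tab-separated file with
#' a header, genes ordered by ascending adjusted p-value and ties broken by
#' gene id.  Numeric columns are written with 12 significant digits, so a
#' write/read cycle is lossless at that precision.
#'
#' @param table A `gene_result_table` as returned by [bsm_select()].
#' @param path Output path.
#' @return Invisibly, the ordered table that was written.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || is.null(table$gene_id))
    stop("'table' must be a gene result table (see bsm_select())")
  ord <- order(table$adj_p_value, table$gene_id)
  out <- table[ord, , drop = FALSE]
  fmt <- out
  for (nm in names(fmt))
    if (is.numeric(fmt[[nm]]) && !is.integer(fmt[[nm]]))
      fmt[[nm]] <- sprintf("%.12g", fmt[[nm]])
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
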