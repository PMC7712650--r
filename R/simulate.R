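#' Specification of a synthetic two-class expression study
#'
#' Captures the data-generating conditions for [simulate_expression()]:
#' Gaussian log2-scale background, a small set of informative genes with a
#' mean shift of `delta` within-group standard deviations in the case
#' class, and blocks of redundant genes sharing a latent factor so their
#' expected within-block correlation is `rho`.
#'
#' @param N Total number of genes.
#' @param M1,M2 Case and control sample counts.
#' @param n_info Number of informative genes (the first `n_info` gene ids).
#' @param delta Effect size in units of the within-group standard
#'   deviation (>= 0).
#' @param n_blocks Number of correlated redundant blocks (may be 0).
#' @param block_size Genes per block; blocks are carved out of the
#'   background genes immediately after the informative ones.
#' @param rho Within-block correlation in `[0, 1)`.
#' @param mu0 Baseline mean on the log2 scale.
#' @param sigma Within-group standard deviation.
#' @param seed Seed for the generator.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(N = 500L, M1 = 20L, M2 = 20L, n_info = 20L,
                            delta = 2, n_blocks = 5L, block_size = 10L,
                            rho = 0.6, mu0 = 7, sigma = 1, seed = 1L) {
  if (n_info > N) stop("'n_info' must not exceed N")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  if (delta < 0) stop("'delta' must be nonnegative")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (n_info + n_blocks * block_size > N)
    stop("informative genes plus blocks exceed N")
  if (M1 < 2L || M2 < 2L) stop("each class needs at least 2 samples")
  structure(list(N = as.integer(N), M1 = as.integer(M1),
                 M2 = as.integer(M2), n_info = as.integer(n_info),
                 delta = delta, n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size), rho = rho,
                 mu0 = mu0, sigma = sigma, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a two-class expression dataset
#'
#' Background genes are i.i.d. Gaussian(`mu0`, `sigma^2`) in every sample.
#' Genes in each redundant block are generated from one per-sample latent
#' Gaussian factor with loading `sqrt(rho)` plus independent noise with
#' loading `sqrt(1 - rho)`, giving expected pairwise within-block
#' correlation `rho`.  Informative genes receive an additional shift of
#' `delta * sigma` in the case samples.  Fully determined by `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `dataset` (an [expression_dataset()]) and
#'   `informative` (character vector of the informative gene ids).
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop("expected a 'simulation_spec'")
  set.seed(spec$seed)
  n <- spec$N
  m <- spec$M1 + spec$M2
  gene_ids <- sprintf("g%04d", seq_len(n))
  sample_ids <- c(sprintf("case%03d", seq_len(spec$M1)),
                  sprintf("ctrl%03d", seq_len(spec$M2)))
  labels <- c(rep(1L, spec$M1), rep(-1L, spec$M2))

  x <- matrix(stats::rnorm(n * m), nrow = n, ncol = m,
              dimnames = list(gene_ids, sample_ids))
  if (spec$n_blocks > 0L) {
    for (bl in seq_len(spec$n_blocks)) {
      rows <- spec$n_info + (bl - 1L) * spec$block_size +
        seq_len(spec$block_size)
      f <- stats::rnorm(m)            # latent factor, one value per sample
      x[rows, ] <- sqrt(spec$rho) * matrix(f, nrow = spec$block_size,
                                           ncol = m, byrow = TRUE) +
        sqrt(1 - spec$rho) * x[rows, ]
    }
  }
  x <- spec$mu0 + spec$sigma * x
  informative <- gene_ids[seq_len(spec$n_info)]
  if (spec$n_info > 0L && spec$delta > 0)
    x[informative, labels == 1L] <- x[informative, labels == 1L] +
      spec$delta * spec$sigma
  list(dataset = expression_dataset(x, labels), informative = informative)
}

#' Simulate gene coordinates and QTL intervals
#'
#' Places genes on 12 chromosomes as non-overlapping 1 kb spans separated
#' by 4 kb gaps, then draws QTL intervals so that a requested fraction of
#' a designated gene subset is fully contained in at least one QTL (one
#' QTL snugly around each covered gene); any remaining QTL budget is
#' placed in gene-free territory beyond the last gene of a chromosome.
#'
#' @param gene_ids Character vector of gene ids to place.
#' @param n_qtls Total number of QTL intervals to produce.
#' @param frac_info_covered Fraction of `target_ids` to cover, in
#'   `[0, 1]`.
#' @param target_ids The designated gene subset; defaults to the first
#'   10 genes (or all of them if fewer).
#' @param seed Seed.
#' @return List with `genes` (named `GRanges` of gene spans) and `qtls`
#'   (named `GRanges` of QTL intervals).
#' @export
simulate_genome_features <- function(gene_ids, n_qtls, frac_info_covered,
                                     target_ids = NULL, seed = 1L) {
  if (frac_info_covered < 0 || frac_info_covered > 1)
    stop("'frac_info_covered' must lie in [0, 1]")
  if (is.null(target_ids))
    target_ids <- utils::head(gene_ids, 10L)
  if (!all(target_ids %in% gene_ids))
    stop("'target_ids' must be a subset of 'gene_ids'")
  set.seed(seed)
  n <- length(gene_ids)
  chrom <- paste0("chr", rep_len(seq_len(12L), n))
  idx_on_chr <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- (idx_on_chr - 1L) * 5000L + 2001L
  genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = start + 999L))
  names(genes) <- gene_ids

  n_cover <- round(frac_info_covered * length(target_ids))
  if (n_cover > n_qtls)
    stop("n_qtls = ", n_qtls, " is too small to cover ", n_cover,
         " genes (one QTL per covered gene)")
  covered <- if (n_cover > 0L) sample(target_ids, n_cover) else character(0)

  qtl_chr <- character(0)
  qtl_start <- integer(0)
  qtl_end <- integer(0)
  if (n_cover > 0L) {
    gi <- genes[covered]
    # a QTL padded into the 4 kb gaps contains exactly its own gene
    qtl_chr <- as.character(GenomicRanges::seqnames(gi))
    qtl_start <- GenomicRanges::start(gi) - 500L
    qtl_end <- GenomicRanges::end(gi) + 500L
  }
  n_extra <- n_qtls - n_cover
  if (n_extra > 0L) {
    # gene-free territory well beyond the last placed gene
    far <- max(start) + 100000L
    qtl_chr <- c(qtl_chr, paste0("chr", rep_len(seq_len(12L), n_extra)))
    qtl_start <- c(qtl_start, far + (seq_len(n_extra) - 1L) * 10000L)
    qtl_end <- c(qtl_end, far + (seq_len(n_extra) - 1L) * 10000L + 4999L)
  }
  qtls <- GenomicRanges::GRanges(
    seqnames = qtl_chr,
    ranges = IRanges::IRanges(start = qtl_start, end = qtl_end))
  names(qtls) <- sprintf("q%03d", seq_along(qtls))
  list(genes = genes, qtls = qtls)
}

#' Simulate gene -> GO-term annotations with a coherent subset
#'
#' Genes in `coherent_subset` share a common core of terms (plus a couple
#' of private ones), so their expected pairwise Jaccard distance is well
#' below that of background genes, which draw their terms uniformly from
#' the vocabulary.
#'
#' @param gene_ids All gene ids to annotate.
#' @param coherent_subset Subset of `gene_ids` sharing the core terms.
#' @param n_terms Vocabulary size (number of distinct term ids).
#' @param n_core Shared core terms per coherent gene.
#' @param n_private Extra random terms per coherent gene.
#' @param n_background Terms drawn per background gene.
#' @param seed Seed.
#' @return An [annotation_map()].
#' @export
simulate_annotations <- function(gene_ids, coherent_subset, n_terms = 100L,
                                 n_core = 5L, n_private = 2L,
                                 n_background = 5L, seed = 1L) {
  if (!all(coherent_subset %in% gene_ids))
    stop("'coherent_subset' must be a subset of 'gene_ids'")
  if (n_terms < n_core + n_private || n_terms < n_background)
    stop("'n_terms' vocabulary too small")
  set.seed(seed)
  vocab <- sprintf("GO:%07d", seq_len(n_terms))
  core <- sample(vocab, n_core)
  mapping <- lapply(stats::setNames(gene_ids, gene_ids), function(g) {
    if (g %in% coherent_subset)
      unique(c(core, sample(setdiff(vocab, core), n_private)))
    else
      sample(vocab, n_background)
  })
  annotation_map(mapping)
}
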