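test_that("window configuration follows K = floor((n - S)/L)", {
  cfg <- window_config(100, 50, 10)
  expect_equal(cfg$K, 5L)
  expect_equal(window_config(23, 10, 4)$K, 3L)
  expect_error(window_config(10, 20, 5), "exceed")
  expect_error(window_config(10, 10, 5), "K < 1")
})

test_that("mean CA and SE reproduce hand arithmetic through the real code path", {
  # two windows of one gene each: a perfect marker (x = y) and its mirror
  # classified by a sign stub -> CA = (1, 0), mean 0.5, SE 0.5
  vals <- rbind(c(1, 1, -1, -1, 1, -1),
                -c(1, 1, -1, -1, 1, -1),
                matrix(0, 1, 6))
  ds <- make_dataset(vals, c(1, 1, -1, -1, 1, -1))
  sign_stub <- function(xtr, ytr) function(xte) ifelse(xte[, 1] >= 0, 1L, -1L)
  res <- sliding_window_accuracy(
    ds, c("g01", "g02", "g03"), window_config(3, 1, 1),
    folds = 3, seed = 1, classifier = sign_stub)
  expect_equal(res$ca, c(1, 0))
  expect_equal(res$mean_ca, 0.5)
  expect_equal(res$se_ca, 0.5)

  # population-form SE on the printed example values
  ca <- c(0.8, 0.9)
  expect_equal(mean(ca), 0.85)
  expect_equal(sqrt(mean((ca - mean(ca))^2)), 0.05)
})

test_that("a majority-class stub scores exactly max(M1, M2)/M", {
  ds <- rand_dataset(6, 8, 4, seed = 2)
  majority_stub <- function(xtr, ytr) {
    maj <- if (sum(ytr == 1) >= sum(ytr == -1)) 1L else -1L
    function(xte) rep(maj, nrow(xte))
  }
  res <- sliding_window_accuracy(
    ds, rownames(ds$values), window_config(6, 2, 2),
    folds = 4, seed = 3, classifier = majority_stub)
  expect_equal(res$mean_ca, 8 / 12)
  expect_equal(res$se_ca, 0)
})

test_that("window accuracy with an SVM is deterministic under a fixed seed", {
  sim <- simulate_expression(simulation_spec(N = 30, M1 = 8, M2 = 8,
                                             n_info = 6, delta = 2,
                                             n_blocks = 0, seed = 4))
  ranked <- sim$dataset
  ids <- rownames(ranked$values)
  r1 <- sliding_window_accuracy(ranked, ids, window_config(30, 10, 5),
                                kernel = "radial", folds = 4, seed = 11)
  r2 <- sliding_window_accuracy(ranked, ids, window_config(30, 10, 5),
                                kernel = "radial", folds = 4, seed = 11)
  expect_identical(r1$ca, r2$ca)
  expect_true(all(r1$ca >= 0 & r1$ca <= 1))
})

test_that("QTL containment counts distinct genes fully inside intervals", {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(100, 40, 100), end = c(200, 60, 200)))
  names(genes) <- c("gIn", "gStraddle", "gWrongChr")
  qtls <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(start = 50, end = 300))
  names(qtls) <- "q1"
  expect_equal(as.integer(qtl_qstat("gIn", genes, qtls)), 1L)
  expect_equal(as.integer(qtl_qstat("gStraddle", genes, qtls)), 0L)
  expect_equal(as.integer(qtl_qstat("gWrongChr", genes, qtls)), 0L)
  v <- qtl_qstat(c("gIn", "gStraddle", "gWrongChr"), genes, qtls)
  expect_equal(as.integer(v), 1L)

  # overlapping QTLs count a gene once; the pair count sees both
  qtls2 <- c(qtls, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = 90, end = 210)))
  names(qtls2) <- c("q1", "q2")
  v2 <- qtl_qstat("gIn", genes, qtls2)
  expect_equal(as.integer(v2), 1L)
  expect_equal(attr(v2, "n_pairs"), 2L)

  expect_warning(qtl_qstat(c("gIn", "gMissing"), genes, qtls), "excluded")
})

test_that("Qstat is monotone in both the QTL set and the gene set", {
  set.seed(5)
  ids <- sprintf("g%02d", 1:20)
  feat <- simulate_genome_features(ids, n_qtls = 8, frac_info_covered = 0.6,
                                   target_ids = ids[1:10], seed = 5)
  sets <- list(ids[1:5], ids[1:12], ids)
  counts <- vapply(sets, function(s)
    as.integer(qtl_qstat(s, feat$genes, feat$qtls)), integer(1))
  expect_true(all(diff(counts) >= 0))
  fewer_qtls <- feat$qtls[1:3]
  expect_lte(as.integer(qtl_qstat(ids, feat$genes, fewer_qtls)),
             as.integer(qtl_qstat(ids, feat$genes, feat$qtls)))
})

test_that("hypergeometric enrichment matches enumeration and its edge cases", {
  expect_equal(qtl_enrichment_pvalue(0, 50, 10, 5), 1)
  expect_equal(qtl_enrichment_pvalue(5, 10, 5, 5), 1 / 252,
               tolerance = 1e-12)
  expect_equal(qtl_enrichment_pvalue(4, 10, 4, 10), 1)  # n = N forces v = V
  p_by_v <- vapply(0:4, qtl_enrichment_pvalue, numeric(1),
                   N = 12, V = 4, n = 6)
  expect_true(all(diff(p_by_v) < 0))
  for (v in 0:4)
    expect_equal(qtl_enrichment_pvalue(v, 12, 4, 6),
                 oracle_hyper_upper(v, 12, 4, 6), tolerance = 1e-12)
  expect_error(qtl_enrichment_pvalue(6, 12, 4, 5), "v > n")
  expect_error(qtl_enrichment_pvalue(2, 12, 14, 5), "V > N")
})

test_that("GO distance is the Jaccard complement with the stated edge rules", {
  expect_equal(go_distance(c("A", "B"), c("A", "B")), 0)
  expect_equal(go_distance(c("A"), c("B", "C")), 1)
  expect_equal(go_distance(c("A", "B"), c("B", "C")), 1 - 1 / 3)
  expect_equal(go_distance(character(0), c("A")), 1)
  expect_error(go_distance(character(0), character(0)), "empty")
})

test_that("average GO distance skips unannotated genes and is order-invariant", {
  ann <- annotation_map(list(g1 = "A", g2 = "A", g3 = "B", g4 = c("A", "B")))
  two <- go_average_distance(c("g1", "g3"), ann)
  expect_equal(two$average, 1)
  expect_equal(two$n_pairs_used, 1L)

  tri <- go_average_distance(c("g1", "g2", "g3"), ann)
  expect_equal(tri$average, 2 / 3)   # distances 0, 1, 1

  same <- go_average_distance(c("g1", "g2"), ann)
  expect_equal(same$average, 0)

  shuffled <- go_average_distance(c("g3", "g1", "g2"), ann)
  expect_equal(shuffled$average, tri$average)

  with_missing <- go_average_distance(c("g1", "g3", "gZ"), ann)
  expect_equal(with_missing$n_unannotated, 1L)
  expect_equal(with_missing$n_pairs_used, 1L)
  expect_error(go_average_distance(c("gX", "gY"), ann), "fewer than 2")
})
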