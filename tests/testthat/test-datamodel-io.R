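test_that("expression dataset construction enforces the two-class contract", {
  vals <- matrix(1:12 + 0, 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  ds <- expression_dataset(vals, c(1, 1, -1, -1))
  expect_equal(nrow(ds$values), 3L)
  expect_equal(ncol(ds$values), 4L)
  expect_equal(sum(ds$labels == 1L), 2L)
  expect_equal(sum(ds$labels == -1L), 2L)

  dup <- vals
  rownames(dup) <- c("g1", "g1", "g3")
  expect_error(expression_dataset(dup, c(1, 1, -1, -1)), "duplicated gene")
  expect_error(expression_dataset(vals, c(1, 1, 1, -1)), "at least 2 samples")
  expect_error(expression_dataset(vals, c(1, 2, -1, -1)), "coded")
  nav <- vals; nav[2, 2] <- NA
  expect_error(expression_dataset(nav, c(1, 1, -1, -1)), "missing")
})

test_that("group summary matches direct computation and its mean identity", {
  ds <- rand_dataset(6, 3, 4, seed = 11)
  gs <- group_summary(ds)
  i <- 4L
  expect_equal(gs$mean_case[i], mean(ds$values[i, ds$labels == 1]))
  expect_equal(gs$var_control[i], var(ds$values[i, ds$labels == -1]))
  expect_equal(gs$mean_all,
               (3 * gs$mean_case + 4 * gs$mean_control) / 7)
  expect_true(all(gs$var_case >= 0 & gs$var_control >= 0))
  expect_equal(gene_covariance(ds, 1, 2),
               cov(ds$values[1, ], ds$values[2, ]))
})

test_that("expression reader round-trips and reconciles labels by id", {
  ds <- rand_dataset(5, 2, 3, seed = 3)
  mp <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_expression(ds, mp, lp)
  back <- read_expression(mp, lp)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)

  # permuting the label rows must not change the dataset
  lab <- read.delim(lp, header = FALSE)
  write.table(lab[rev(seq_len(nrow(lab))), ], lp, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_equal(read_expression(mp, lp)$labels, ds$labels)

  # case/control tokens map to +1/-1
  writeLines(paste(colnames(ds$values),
                   ifelse(ds$labels == 1, "case", "control"), sep = "\t"),
             lp)
  expect_equal(read_expression(mp, lp)$labels, ds$labels)
})

test_that("expression reader reports malformed input precisely", {
  ds <- rand_dataset(4, 2, 2, seed = 5)
  mp <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_expression(ds, mp, lp)

  # a sample missing from the labels file
  lab <- read.delim(lp, header = FALSE)
  write.table(lab[-2, ], lp, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_expression(mp, lp), "not in labels")

  # duplicated gene id
  write_expression(ds, mp, lp)
  lines <- readLines(mp)
  lines[3] <- lines[2]
  writeLines(lines, mp)
  expect_error(read_expression(mp, lp), "duplicated gene")

  # non-numeric cell named by gene and sample
  write_expression(ds, mp, lp)
  lines <- readLines(mp)
  lines[2] <- sub("\t[-0-9.]+$", "\tnot_a_number", lines[2])
  writeLines(lines, mp)
  expect_error(read_expression(mp, lp), "non-numeric.*g01", )
})

test_that("interval reader honours both coordinate dialects", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tq1", "chr2\t0\t50\tq2"), p)
  gr <- read_intervals(p, dialect = "bed0")
  expect_equal(GenomicRanges::start(gr), c(100L, 1L))
  expect_equal(GenomicRanges::end(gr), c(200L, 50L))
  expect_equal(names(gr), c("q1", "q2"))

  writeLines("chr1\t100\t200\tq1", p)
  gr1 <- read_intervals(p, dialect = "inclusive1")
  expect_equal(GenomicRanges::start(gr1), 100L)
  expect_equal(GenomicRanges::end(gr1), 200L)

  writeLines("chr1\t300\t200\tq1", p)
  expect_error(read_intervals(p, dialect = "inclusive1"), "stop < start")
  writeLines("chr1\tabc\t200\tq1", p)
  expect_error(read_intervals(p, dialect = "inclusive1"), "non-numeric")
})

test_that("annotation reader collapses duplicates and defaults to empty sets", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tt1", "g1\tt1", "g1\tt2", "g2\tt3", "g3\tt1"), p)
  ann <- read_annotations(p)
  expect_setequal(go_terms(ann, "g1"), c("t1", "t2"))
  expect_equal(length(ann$mapping), 3L)
  expect_identical(go_terms(ann, "unannotated_gene"), character(0))

  writeLines(character(0), p)
  expect_warning(empty <- read_annotations(p), "empty")
  expect_equal(length(empty$mapping), 0L)

  # category column filtering
  writeLines(c("g1\tt1\tMF", "g1\tt2\tBP", "g2\tt3\tMF"), p)
  mf <- read_annotations(p, category = "MF")
  expect_setequal(go_terms(mf, "g1"), "t1")
  expect_equal(mf$category, "MF")
})

test_that("result writer orders by adjusted p (gene id on ties) and round-trips", {
  res <- structure(
    data.frame(gene_id = c("gB", "gA", "gC"),
               mrmr_weight = c(1.23456789012e-3, 2, 3),
               svm_weight = c(0.1, 0.2, 0.3),
               sd_score = c(0.5, 0.6, 0.7),
               w_stat = c(10, 20, 30),
               z_score = c(-1, 0, 1),
               p_value = c(0.8, 0.2, 0.8),
               adj_p_value = c(0.9, 0.4, 0.9),
               selected = c(FALSE, FALSE, FALSE),
               stringsAsFactors = FALSE),
    class = c("gene_result_table", "data.frame"))
  p <- tempfile(fileext = ".tsv")
  write_results(res, p)
  back <- read.delim(p, stringsAsFactors = FALSE)
  expect_equal(back$gene_id, c("gA", "gB", "gC"))  # tie gB/gC by id
  expect_equal(back$mrmr_weight[2], 1.23456789012e-3, tolerance = 1e-12)
  expect_true(all(diff(back$adj_p_value) >= 0))
})
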