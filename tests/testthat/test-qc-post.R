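test_that("quality indicators match a hand-built single cell", {
  # one cell: 100 transcripts over 50 genes, 10 of them mitochondrial
  counts <- matrix(0L, 60, 1)
  counts[1:49, 1] <- c(rep(2L, 41), rep(1L, 8))  # 90 transcripts, 49 genes
  counts[50, 1] <- 10L                           # mito gene: 10 transcripts
  mito <- c(rep(FALSE, 49), TRUE, rep(FALSE, 10))
  m <- toy_matrix(counts, mito = mito)
  qc <- compute_qc_indicators(m)
  expect_equal(qc$median[qc$indicator == "genes_per_cell"], 50)
  expect_equal(qc$median[qc$indicator == "transcripts_per_cell"], 100)
  expect_equal(qc$median[qc$indicator == "mito_rate"], 0.10)
  expect_equal(qc$mean, qc$median)  # single cell: all statistics coincide
})

test_that("cells without transcripts get mito rate 0 with a warning", {
  counts <- matrix(c(5L, 0L), 1, 2)
  m <- toy_matrix(counts)
  expect_warning(qc <- compute_qc_indicators(m), "0 transcripts")
  expect_equal(qc$q25[qc$indicator == "mito_rate"], 0)
})

test_that("each filter rule drops what it should, in order", {
  # 4 genes x 4 cells; gene 4 mitochondrial
  counts <- rbind(
    c(10L, 10L, 10L, 10L),  # g1 in all cells
    c(5L, 5L, 0L, 5L),      # g2 in 3 cells
    c(1L, 0L, 0L, 0L),      # g3 in 1 cell -> dropped (min_cells 2)
    c(1L, 0L, 0L, 6L)       # g4 (mito), in 2 cells
  )
  m <- toy_matrix(counts, mito = c(FALSE, FALSE, FALSE, TRUE))
  p <- filter_params(min_cells_per_gene = 2, min_genes_per_cell = 2,
                     max_mito_rate = 0.20)
  f <- filter_matrix(m, p)
  rep <- attr(f, "filter_report")
  # pass 1 drops g3 (1 cell); once cells 3 and 4 are gone, g4 falls to
  # 1 cell and goes in the second pass
  expect_equal(rep$dropped[rep$rule == "min_cells_per_gene"], 2)
  # cell 3 has only g1 left (1 gene < 2) -> dropped
  expect_equal(rep$dropped[rep$rule == "min_genes_per_cell"], 1)
  # cell 4: mito 6 of 21 = 0.286 > 0.20 -> dropped (cell 1: 1/16 is fine)
  expect_equal(rep$dropped[rep$rule == "max_mito_rate"], 1)
  expect_equal(f$barcodes, c("BC0001", "BC0002"))
  expect_equal(f$features$gene_id, c("G001", "G002"))
})

test_that("the documented defaults drop undersized genes and cells", {
  # gene expressed in 2 cells < default 3 -> dropped
  n_genes <- 260
  counts <- matrix(1L, n_genes, 4)
  counts[1, 3:4] <- 0L                     # gene 1 in 2 cells < 3
  counts[150:n_genes, 2] <- 0L             # cell 2 keeps 148 genes < 200
  m <- toy_matrix(counts)
  f <- filter_matrix(m, filter_params())
  rep <- attr(f, "filter_report")
  expect_equal(rep$dropped[rep$rule == "min_cells_per_gene"], 1)
  expect_equal(rep$dropped[rep$rule == "min_genes_per_cell"], 1)
  expect_false("BC0002" %in% f$barcodes)
})

test_that("a cell over the mitochondrial ceiling is dropped", {
  counts <- matrix(2L, 300, 5)
  counts[1, 1] <- 200L  # mito gene: 200/798 = 0.25 in cell 1
  m <- toy_matrix(counts, mito = c(TRUE, rep(FALSE, 299)))
  f <- filter_matrix(m, filter_params(max_mito_rate = 0.20))
  expect_equal(f$barcodes, sprintf("BC%04d", 2:5))
})

test_that("filtering is idempotent", {
  sim <- simulate_count_matrix(sim_config(
    n_cells_per_species = c(human = 80, mouse = 80),
    transcripts_per_cell = c(400, 2), genes_per_species = 60, seed = 12
  ))
  p <- filter_params(min_cells_per_gene = 3, min_genes_per_cell = 2,
                     max_mito_rate = 0.2)
  f1 <- filter_matrix(sim$matrix, p)
  f2 <- filter_matrix(f1, p)
  expect_equal(as.matrix(f2$counts), as.matrix(f1$counts))
  expect_equal(f2$barcodes, f1$barcodes)
  rep2 <- attr(f2, "filter_report")
  expect_true(all(rep2$dropped == 0))
})

test_that("filtering everything away is an explicit error with a report", {
  counts <- matrix(1L, 5, 3)
  m <- toy_matrix(counts)
  expect_error(filter_matrix(m, filter_params(min_genes_per_cell = 100)),
               class = "empty_result_error")
})

test_that("normalization evaluates the log2 counts-per-ten-thousand formula", {
  counts <- matrix(c(10L, 990L, 1000L, 0L), 2, 2)
  m <- toy_matrix(counts)
  norm <- normalize_log(m)
  # gene with 10 of 1000 transcripts: X = 0.01 -> log2(101)
  expect_equal(norm[1, 1], log2(101))
  # a cell entirely on one gene: X = 1 -> log2(10001)
  expect_equal(norm[1, 2], log2(10001))
  # zeros stay zero (sparsity preserved)
  expect_equal(norm[2, 2], 0)
  expect_equal(length(norm@x), length(m$counts@x))
})

test_that("normalization is per-cell depth invariant and monotone", {
  counts <- matrix(c(10L, 90L, 30L, 70L), 2, 2)
  m1 <- toy_matrix(counts)
  m2 <- toy_matrix(counts * 13L)
  expect_equal(as.matrix(normalize_log(m1)), as.matrix(normalize_log(m2)))
  # monotone in the within-cell fraction
  col <- as.matrix(normalize_log(m1))[, 2]
  expect_equal(order(col), order(counts[, 2]))
})

test_that("zero-total cells cannot be normalized", {
  counts <- matrix(c(5L, 0L), 1, 2)
  m <- toy_matrix(counts)
  expect_error(normalize_log(m), class = "zero_total_error")
})
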