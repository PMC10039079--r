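test_that("read layout validates its spans", {
  l <- read_layout()
  expect_equal(l$barcode, c(1L, 16L))
  expect_equal(l$umi, c(17L, 28L))
  expect_error(read_layout(barcode = c(1, 16), umi = c(10, 21)),
               class = "layout_error")
  expect_error(read_layout(r1_length = 20, umi = c(17, 28)),
               class = "layout_error")
  expect_error(read_layout(barcode = c(5, 4)), class = "layout_error")
})

test_that("Matrix Market directories parse with sidecars and report errors", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(d, "matrix.mtx"))
  writeLines(c("g1\thuman\tFALSE", "g2\thuman\tFALSE", "g3\tmouse\tTRUE"),
             file.path(d, "features.tsv"))
  writeLines(c("AAAA", "CCCC"), file.path(d, "barcodes.tsv"))
  m <- read_count_matrix(d)
  expect_equal(unname(Matrix::colSums(m$counts)), c(5, 2))
  expect_equal(m$features$gene_id, c("g1", "g2", "g3"))
  expect_true(m$features$mito[3])

  # empty (0 nonzeros) is a valid matrix
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(d, "matrix.mtx"))
  m0 <- read_count_matrix(d)
  expect_equal(unname(Matrix::colSums(m0$counts)), c(0, 0))

  # dimension mismatch between matrix and features names the files
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 2 1", "1 1 5"),
             file.path(d, "matrix.mtx"))
  err <- expect_error(read_count_matrix(d), class = "format_error")
  expect_match(conditionMessage(err), "features.tsv")
})

test_that("count matrices round-trip through MTX exactly", {
  sim <- simulate_count_matrix(sim_config(
    n_cells_per_species = c(human = 30, mouse = 30),
    transcripts_per_cell = c(200, 2), genes_per_species = 40, seed = 3
  ))
  d <- withr::local_tempdir()
  write_count_matrix(sim$matrix, d)
  back <- read_count_matrix(d)
  expect_equal(as.matrix(back$counts), as.matrix(sim$matrix$counts))
  expect_equal(back$features, sim$matrix$features)
  expect_equal(back$barcodes, sim$matrix$barcodes)
  expect_equal(back$raw_reads, sim$matrix$raw_reads)
})

test_that("barcode strings containing N survive the round trip verbatim", {
  m <- toy_two_gene_matrix(c(3, 1), c(0, 2),
                           barcodes = c("ACGTN", "NNNNA"))
  d <- withr::local_tempdir()
  write_count_matrix(m, d)
  expect_equal(read_count_matrix(d)$barcodes, c("ACGTN", "NNNNA"))
})

test_that("tagged-read TSVs round-trip", {
  reads <- tibble::tibble(
    barcode = c("AAAA", "CCCC"), umi = c("GG", "TT"),
    gene = c("g1", "UNASSIGNED"), species = c("human", "UNASSIGNED")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tagged_reads(reads, path)
  expect_equal(read_tagged_reads(path), reads)
})

test_that("count matrix invariants are enforced", {
  ft <- feature_table(c("g1", "g2"), c("human", "mouse"))
  expect_error(count_matrix(matrix(1, 2, 2), ft, c("A", "A")),
               class = "format_error")
  expect_error(count_matrix(matrix(-1, 2, 1), ft, "A"),
               class = "format_error")
  # raw reads below the transcript total is impossible
  expect_error(count_matrix(matrix(5, 2, 1), ft, "A", raw_reads = 3),
               class = "format_error")
})

test_that("FASTQ parsing recovers simulated reads exactly at zero error", {
  sim <- small_read_sim()
  d <- withr::local_tempdir()
  write_fastq_pair(sim$reads, file.path(d, "r1.fastq"),
                   file.path(d, "r2.fastq"), catalog = sim$catalog)
  tagged <- parse_fastq_pair(file.path(d, "r1.fastq"), file.path(d, "r2.fastq"),
                             catalog = sim$catalog, features = sim$features)
  expect_equal(tagged$barcode, sim$reads$barcode)
  expect_equal(tagged$umi, sim$reads$umi)
  expect_equal(tagged$gene, sim$reads$gene)
  expect_equal(tagged$species, sim$reads$species)
  expect_equal(attr(tagged, "n_input"), nrow(sim$reads))
  expect_equal(attr(tagged, "n_dropped"), 0L)
})

test_that("unmatched cDNA is UNASSIGNED and N-containing reads are dropped", {
  catalog <- c(g1 = strrep("ACGT", 125), g2 = strrep("GGCA", 125))
  features <- feature_table(c("g1", "g2"), c("human", "mouse"))
  layout <- read_layout()
  d <- withr::local_tempdir()
  reads <- tibble::tibble(
    barcode = c(strrep("A", 16), strrep("C", 16), paste0("N", strrep("A", 15))),
    umi = c(strrep("G", 12), strrep("T", 12), strrep("G", 12)),
    gene = c("g1", "g2", "g1"),
    species = c("human", "mouse", "human")
  )
  write_fastq_pair(reads, file.path(d, "r1.fastq"), file.path(d, "r2.fastq"),
                   layout = layout, catalog = catalog)
  # overwrite R2 of the second read with sequence absent from the catalog
  lines <- readLines(file.path(d, "r2.fastq"))
  lines[6] <- strrep("T", 70)
  writeLines(lines, file.path(d, "r2.fastq"))
  tagged <- parse_fastq_pair(file.path(d, "r1.fastq"), file.path(d, "r2.fastq"),
                             layout = layout, catalog = catalog,
                             features = features)
  expect_equal(nrow(tagged), 2L)            # N-barcode read dropped
  expect_equal(attr(tagged, "n_dropped"), 1L)
  expect_equal(attr(tagged, "n_input"), 3L) # dropped + emitted = input
  expect_equal(tagged$gene, c("g1", "UNASSIGNED"))
  expect_equal(tagged$species, c("human", "UNASSIGNED"))
})

test_that("out-of-sync FASTQ pairs and short R1 are rejected", {
  catalog <- c(g1 = strrep("ACGT", 125))
  features <- feature_table("g1", "human")
  d <- withr::local_tempdir()
  r1 <- file.path(d, "r1.fastq")
  r2 <- file.path(d, "r2.fastq")
  writeLines(c("@a", strrep("A", 30), "+", strrep("I", 30),
               "@b", strrep("A", 30), "+", strrep("I", 30)), r1)
  writeLines(c("@a", strrep("A", 70), "+", strrep("I", 70)), r2)
  expect_error(parse_fastq_pair(r1, r2, catalog = catalog,
                                features = features),
               class = "synchronization_error")
  writeLines(c("@a", strrep("A", 10), "+", strrep("I", 10)), r1)
  expect_error(parse_fastq_pair(r1, r2, catalog = catalog,
                                features = features),
               class = "layout_error")
})
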