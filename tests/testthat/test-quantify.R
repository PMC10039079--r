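features2 <- function() feature_table(c("g1", "g2"), c("human", "mouse"))

test_that("reads sharing a (barcode, umi, gene) key collapse to one transcript", {
  reads <- tibble::tibble(
    barcode = rep("AAAA", 5), umi = rep("CCCC", 5),
    gene = rep("g1", 5), species = rep("human", 5)
  )
  m <- build_count_matrix(reads, "AAAA", features2())
  expect_equal(sum(m$counts), 1)
  expect_equal(unname(m$raw_reads), 5)
})

test_that("the same barcode and UMI on two genes are two transcripts", {
  reads <- tibble::tibble(
    barcode = rep("AAAA", 2), umi = rep("CCCC", 2),
    gene = c("g1", "g2"), species = c("human", "mouse")
  )
  m <- build_count_matrix(reads, "AAAA", features2())
  expect_equal(sum(m$counts), 2)
})

test_that("unassigned reads count toward depth but never toward transcripts", {
  reads <- tibble::tibble(
    barcode = rep("AAAA", 3), umi = c("C", "G", "T"),
    gene = c("g1", "UNASSIGNED", "UNASSIGNED"),
    species = c("human", "UNASSIGNED", "UNASSIGNED")
  )
  m <- build_count_matrix(reads, "AAAA", features2())
  expect_equal(sum(m$counts), 1)
  expect_equal(unname(m$raw_reads), 3)
})

test_that("genes missing from the feature table are a consistency error", {
  reads <- tibble::tibble(barcode = "A", umi = "C", gene = "nope",
                          species = "human")
  expect_error(build_count_matrix(reads, "A", features2()),
               class = "consistency_error")
})

test_that("deduplication is idempotent", {
  sim <- small_read_sim()
  cells <- sim$truth$barcode
  m1 <- build_count_matrix(sim$reads, cells, sim$features)
  # echo the matrix back into a read stream of one read per transcript
  echo <- dplyr::distinct(sim$reads, barcode, umi, gene, species)
  m2 <- build_count_matrix(echo, cells, sim$features)
  expect_equal(as.matrix(m1$counts), as.matrix(m2$counts))
})

test_that("UMI collision losses match the birthday-problem expectation", {
  # n transcripts of one gene in one cell: expected loss n(n-1)/2 / 4^12
  n <- 20000
  umis <- withr::with_seed(77, {
    m <- matrix(sample(c("A", "C", "G", "T"), n * 12, replace = TRUE), n)
    do.call(paste0, as.data.frame(m))
  })
  reads <- tibble::tibble(barcode = "AAAA", umi = umis, gene = "g1",
                          species = "human")
  m <- build_count_matrix(reads, "AAAA", features2())
  deficit <- n - sum(m$counts)
  expected <- n * (n - 1) / 2 / 4^12
  expect_lt(abs(deficit - expected), 3 * sqrt(expected))
})

test_that("binomial thinning retains the expected read fraction", {
  reads <- tibble::tibble(
    barcode = rep(sprintf("BC%03d", 1:100), each = 100),
    umi = "U", gene = "g1", species = "human"
  )
  # 10,000 reads over 100 cells at target depth 50 -> p = 0.5
  out <- downsample_reads(reads, unique(reads$barcode), 50, seed = 19)
  expect_equal(attr(out, "retention_prob"), 0.5)
  band <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.5)
  expect_gte(nrow(out), band[1])
  expect_lte(nrow(out), band[2])
})

test_that("shallow data passes through with a warning", {
  reads <- tibble::tibble(barcode = rep("A", 10), umi = as.character(1:10),
                          gene = "g1", species = "human")
  expect_warning(out <- downsample_reads(reads, "A", 1e6), "no downsampling")
  expect_equal(nrow(out), 10)
  expect_equal(attr(out, "retention_prob"), 1)
})

test_that("thinning preserves species proportions in expectation", {
  pvals <- vapply(1:5, function(seed) {
    sim <- small_read_sim(seed = seed)
    kept <- downsample_reads(sim$reads, sim$truth$barcode, 100, seed = seed)
    before <- table(sim$reads$species)
    after <- table(kept$species)[names(before)]
    suppressWarnings(
      stats::chisq.test(as.numeric(after),
                        p = as.numeric(before) / sum(before))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("tube splitting partitions the matrix and conserves totals", {
  sim <- simulate_count_matrix(sim_config(
    n_cells_per_species = c(human = 100, mouse = 100),
    transcripts_per_cell = c(100, 2), genes_per_species = 30, seed = 4
  ))
  m <- sim$matrix
  tubes <- split_tubes(m, n_tubes = 4, seed = 2)
  expect_length(tubes, 4)
  expect_setequal(unlist(lapply(tubes, function(t) t$barcodes)), m$barcodes)
  expect_equal(sum(vapply(tubes, function(t) length(t$barcodes), 1)),
               length(m$barcodes))
  # per-gene totals add up across tubes
  per_gene <- Reduce(`+`, lapply(tubes, function(t) Matrix::rowSums(t$counts)))
  expect_equal(per_gene, Matrix::rowSums(m$counts))
  # identity partition
  one <- split_tubes(m, n_tubes = 1)
  expect_equal(as.matrix(one[[1]]$counts), as.matrix(m$counts))
  expect_error(split_tubes(m, n_tubes = 1000), class = "config_error")
})

test_that("tube sizes follow the multinomial and tubes have comparable QC", {
  sim <- simulate_count_matrix(sim_config(
    n_cells_per_species = c(human = 400, mouse = 400),
    transcripts_per_cell = c(500, 5), genes_per_species = 50, seed = 6
  ))
  tubes <- split_tubes(sim$matrix, n_tubes = 2, seed = 3)
  sizes <- vapply(tubes, function(t) length(t$barcodes), 1)
  band <- qbinom(c(5e-4, 1 - 5e-4), 800, 1 / 2)
  expect_true(all(sizes >= band[1] & sizes <= band[2]))
  meds <- vapply(tubes, function(t) {
    compute_qc_indicators(t)$median[2]
  }, numeric(1))
  expect_lt(abs(meds[1] - meds[2]) / mean(meds), 0.10)
})
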