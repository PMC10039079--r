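#' Build a deduplicated count matrix from tagged reads
#'
#' Reads sharing a (barcode, UMI, gene) key are one transcript; exact string
#' equality on all three components defines the key (no UMI error-collapsing).
#' Only reads from cell-associated barcodes with an assigned gene contribute
#' transcripts, but every read of a called barcode — assigned or not — counts
#' towards its raw-read depth.
#'
#' @param reads Tibble of tagged reads (barcode, umi, gene, species).
#' @param cells A `cell_call` from [call_cells()] or [manual_threshold()], or
#'   a character vector of barcodes to keep.
#' @param features Feature table ([feature_table()]); every assigned gene in
#'   `reads` must appear in it.
#' @return A [count_matrix()] over the called barcodes (features define the
#'   row set, called barcodes the column set; barcodes without reads keep
#'   zero columns).
#' @export
build_count_matrix <- function(reads, cells, features) {
  barcodes <- if (inherits(cells, "cell_call")) cells$barcodes else
    as.character(cells)
  features <- validate_features(features)
  kept <- filter(reads, .data$barcode %in% barcodes)
  raw_reads <- count(kept, .data$barcode, name = "raw")
  assigned <- filter(kept, .data$gene != UNASSIGNED)
  bad <- setdiff(unique(assigned$gene), features$gene_id)
  if (length(bad)) {
    abort(sprintf("genes absent from the feature table: %s",
                  paste(utils::head(bad, 3), collapse = ", ")),
          class = "consistency_error")
  }
  dedup <- distinct(assigned, .data$barcode, .data$umi, .data$gene)
  cm <- Matrix::sparseMatrix(
    i = match(dedup$gene, features$gene_id),
    j = match(dedup$barcode, barcodes),
    x = 1,
    dims = c(nrow(features), length(barcodes))
  )
  raw <- setNames(rep(0, length(barcodes)), barcodes)
  raw[raw_reads$barcode] <- raw_reads$raw
  count_matrix(cm, features, barcodes, raw_reads = unname(raw))
}

#' Downsample raw reads to a target average depth
#'
#' Unbiased binomial thinning: each read is independently retained with
#' probability `p = target_depth * n_cells / total_raw_reads`, where
#' `total_raw_reads` counts reads belonging to cell-associated barcodes. The
#' retained total therefore has expectation `target_depth * n_cells`. If the
#' data is already shallower than the target the stream passes through
#' unchanged with a warning.
#'
#' @inheritParams build_count_matrix
#' @param target_depth Target raw reads per analyzed cell, on average.
#' @param seed Integer seed for the thinning draws.
#' @return A tibble of retained tagged reads, with attribute
#'   `retention_prob`.
#' @export
downsample_reads <- function(reads, cells, target_depth, seed = 1L) {
  stopifnot(target_depth > 0)
  barcodes <- if (inherits(cells, "cell_call")) cells$barcodes else
    as.character(cells)
  total <- sum(reads$barcode %in% barcodes)
  wanted <- target_depth * length(barcodes)
  if (total <= wanted) {
    warn(sprintf(
      "only %g raw reads per cell available (target %g): no downsampling",
      total / length(barcodes), target_depth))
    out <- reads
    attr(out, "retention_prob") <- 1
    return(out)
  }
  p <- wanted / total
  keep <- withr::with_seed(seed, runif(nrow(reads)) < p)
  out <- reads[keep, ]
  attr(out, "retention_prob") <- p
  out
}

#' Split a count matrix into PCR tubes
#'
#' Barcodes (beads) are assigned to tubes uniformly at random, mirroring the
#' physical split of the bead suspension into PCR tubes; the tubes partition
#' the input matrix (pairwise disjoint, union equal to the input).
#'
#' @param m A [count_matrix()].
#' @param n_tubes Number of tubes.
#' @param seed Integer seed for the assignment.
#' @return A list of `n_tubes` [count_matrix()] objects.
#' @export
split_tubes <- function(m, n_tubes = 8L, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"), n_tubes >= 1)
  n_bc <- length(m$barcodes)
  if (n_tubes > n_bc) {
    abort(sprintf("cannot split %d barcodes into %d tubes", n_bc, n_tubes),
          class = "config_error")
  }
  tube <- withr::with_seed(seed,
                           sample.int(n_tubes, n_bc, replace = TRUE))
  lapply(seq_len(n_tubes), function(t) {
    subset_count_matrix(m, barcodes = m$barcodes[tube == t])
  })
}
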