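#' Quality indicators of a count matrix
#'
#' Per-cell gene diversity (nonzero genes), transcript totals and
#' mitochondrial transcript rate, summarized over cells by median, quartiles
#' and mean. A cell with zero transcripts gets a mitochondrial rate of 0 (with
#' a warning); such cells should normally be removed by filtering first.
#'
#' @param m A [count_matrix()].
#' @return A tibble of class `qc_indicators` with one row per indicator
#'   (genes_per_cell, transcripts_per_cell, mito_rate) and columns median,
#'   q25, q75, mean.
#' @export
compute_qc_indicators <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(m$barcodes) < 1) {
    abort("empty matrix: no barcodes to compute indicators on",
          class = "insufficient_data_error")
  }
  tot <- barcode_totals(m)
  if (any(tot$transcripts == 0)) {
    warn(sprintf("%d cell(s) with 0 transcripts: mitochondrial rate set to 0",
                 sum(tot$transcripts == 0)))
  }
  mito_rate <- if_else(tot$transcripts == 0, 0,
                       tot$mito_transcripts / tot$transcripts)
  stat_row <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(median = q[2], q25 = q[1], q75 = q[3], mean = mean(x))
  }
  out <- bind_rows(
    genes_per_cell = stat_row(tot$genes),
    transcripts_per_cell = stat_row(tot$transcripts),
    mito_rate = stat_row(mito_rate),
    .id = "indicator"
  )
  class(out) <- c("qc_indicators", class(out))
  out
}

#' Cell and gene filter parameters
#'
#' The standard post-processing filters: a gene must be expressed in at least
#' `min_cells_per_gene` cells, a cell must express at least
#' `min_genes_per_cell` genes, and a cell's mitochondrial transcript rate must
#' not exceed `max_mito_rate`.
#'
#' @param min_cells_per_gene Minimum cells expressing a gene (default 3).
#' @param min_genes_per_cell Minimum genes per cell (default 200).
#' @param max_mito_rate Maximum mitochondrial transcript rate per cell
#'   (default 0.20).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_cells_per_gene = 3L,
                          min_genes_per_cell = 200L,
                          max_mito_rate = 0.20) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0,
            max_mito_rate >= 0, max_mito_rate <= 1)
  structure(
    list(min_cells_per_gene = as.integer(min_cells_per_gene),
         min_genes_per_cell = as.integer(min_genes_per_cell),
         max_mito_rate = max_mito_rate),
    class = "filter_params"
  )
}

#' Filter genes and cells of a count matrix
#'
#' Applies the three filters in a fixed order — (1) drop genes expressed in
#' fewer than `min_cells_per_gene` cells; (2) drop cells with fewer than
#' `min_genes_per_cell` genes, counted on the remaining genes; (3) drop cells
#' whose mitochondrial rate, computed on the remaining genes, exceeds
#' `max_mito_rate` — and repeats the pass until nothing changes, since
#' removing cells can push a gene back under the first rule. The fixed point
#' makes the operation idempotent: filtering a filtered matrix changes
#' nothing.
#'
#' @param m A [count_matrix()].
#' @param params A [filter_params()].
#' @return The filtered [count_matrix()] with attribute `filter_report`, a
#'   tibble of dropped genes/cells per rule (accumulated over passes).
#' @export
filter_matrix <- function(m, params = filter_params()) {
  stopifnot(inherits(m, "count_matrix"), inherits(params, "filter_params"))
  dropped <- c(min_cells_per_gene = 0, min_genes_per_cell = 0,
               max_mito_rate = 0)
  out <- m
  repeat {
    cells_per_gene <- Matrix::rowSums(out$counts > 0)
    keep_genes <- cells_per_gene >= params$min_cells_per_gene
    m1 <- subset_count_matrix(out, genes = out$features$gene_id[keep_genes])

    genes_per_cell <- Matrix::colSums(m1$counts > 0)
    keep1 <- genes_per_cell >= params$min_genes_per_cell
    m2 <- subset_count_matrix(m1, barcodes = m1$barcodes[keep1])

    tot <- Matrix::colSums(m2$counts)
    mito <- Matrix::colSums(m2$counts[m2$features$mito, , drop = FALSE])
    rate <- ifelse(tot == 0, 0, mito / tot)
    keep2 <- rate <= params$max_mito_rate
    out <- subset_count_matrix(m2, barcodes = m2$barcodes[keep2])

    pass <- c(sum(!keep_genes), sum(!keep1), sum(!keep2))
    dropped <- dropped + pass
    if (all(pass == 0) || length(out$barcodes) == 0 ||
        nrow(out$features) == 0) {
      break
    }
  }
  report <- tibble(
    rule = names(dropped), unit = c("genes", "cells", "cells"),
    dropped = unname(dropped)
  )
  if (length(out$barcodes) == 0 || nrow(out$features) == 0) {
    abort(paste0(
      "filtering removed everything (dropped: ",
      paste(sprintf("%d %s by %s", report$dropped, report$unit, report$rule),
            collapse = "; "), ")"),
      class = "empty_result_error")
  }
  attr(out, "filter_report") <- report
  out
}

#' Log counts-per-ten-thousand normalization
#'
#' Each entry becomes `log2(10000 * X + 1)` with `X` the fraction of the
#' cell's transcripts falling on that gene, i.e. counts are rescaled to a
#' common depth of ten thousand per cell before the log. Zeros map to zeros,
#' so sparsity is preserved, and the result is invariant to the cell's
#' sequencing depth.
#'
#' @param m A [count_matrix()].
#' @return A sparse real-valued `dgCMatrix` (genes x barcodes) of normalized
#'   expression.
#' @export
normalize_log <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) {
    abort(sprintf(
      "%d cell(s) with 0 transcripts cannot be normalized; filter first",
      sum(tot == 0)), class = "zero_total_error")
  }
  norm <- m$counts
  norm@x <- log2(10000 * norm@x / rep.int(tot, diff(norm@p)) + 1)
  norm
}
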