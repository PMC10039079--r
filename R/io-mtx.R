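#' Read a sparse count matrix from a Matrix Market directory
#'
#' Expects the usual single-cell trio: `matrix.mtx` (coordinate format,
#' 1-based, genes as rows), `features.tsv` (columns gene_id, species, mito)
#' and `barcodes.tsv` (one barcode per line). An optional `raw_reads.tsv`
#' (barcode, raw_reads) restores pre-deduplication depth accounting; without
#' it raw reads default to the transcript totals.
#'
#' @param path Directory containing the three files.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  ftsv <- file.path(path, "features.tsv")
  btsv <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, ftsv, btsv)) {
    if (!file.exists(f)) {
      abort(sprintf("missing file: %s", f), class = "format_error")
    }
  }
  counts <- tryCatch(
    as(Matrix::readMM(mtx), "CsparseMatrix"),
    error = function(e) {
      abort(sprintf("malformed Matrix Market file %s: %s", mtx,
                    conditionMessage(e)),
            class = "format_error")
    }
  )
  features <- readr::read_tsv(
    ftsv,
    col_names = c("gene_id", "species", "mito"),
    col_types = readr::cols(
      gene_id = readr::col_character(),
      species = readr::col_character(),
      mito = readr::col_logical()
    ),
    progress = FALSE
  )
  barcodes <- readr::read_tsv(
    btsv, col_names = "barcode",
    col_types = readr::cols(barcode = readr::col_character()),
    progress = FALSE
  )$barcode
  if (nrow(features) != nrow(counts)) {
    abort(sprintf(
      "%s declares %d genes but %s has %d rows",
      mtx, nrow(counts), ftsv, nrow(features)), class = "format_error")
  }
  if (length(barcodes) != ncol(counts)) {
    abort(sprintf(
      "%s declares %d barcodes but %s has %d rows",
      mtx, ncol(counts), btsv, length(barcodes)), class = "format_error")
  }
  if (length(counts@x) && min(counts@x) < 0) {
    abort(sprintf("negative entries in %s", mtx), class = "format_error")
  }
  raw <- NULL
  rtsv <- file.path(path, "raw_reads.tsv")
  if (file.exists(rtsv)) {
    rr <- readr::read_tsv(rtsv, col_types = "cd", progress = FALSE)
    raw <- rr$raw_reads[match(barcodes, rr$barcode)]
  }
  count_matrix(counts, features, barcodes, raw_reads = raw)
}

#' Write a count matrix as a Matrix Market directory
#'
#' Writes `matrix.mtx` (coordinate integer, 1-based, genes as rows),
#' `features.tsv`, `barcodes.tsv` and `raw_reads.tsv` so that
#' [read_count_matrix()] round-trips the object exactly.
#'
#' @param m A [count_matrix()].
#' @param path Output directory, created if needed.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(sprintf("cannot create directory %s", path), class = "io_error")
  }
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  readr::write_tsv(m$features, file.path(path, "features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(tibble(barcode = m$barcodes),
                   file.path(path, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(
    tibble(barcode = m$barcodes, raw_reads = unname(m$raw_reads)),
    file.path(path, "raw_reads.tsv")
  )
  invisible(path)
}

#' Read or write tagged reads as TSV
#'
#' A tagged read is one sequencing read reduced to its (barcode, umi, gene,
#' species) content after barcode extraction and gene assignment; the file has
#' a header with those four columns.
#'
#' @param path TSV file path.
#' @return `read_tagged_reads()`: a tibble with columns barcode, umi, gene,
#'   species. `write_tagged_reads()`: `path`, invisibly.
#' @export
read_tagged_reads <- function(path) {
  reads <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  need <- c("barcode", "umi", "gene", "species")
  if (!all(need %in% names(reads))) {
    abort(sprintf("%s must have columns %s", path,
                  paste(need, collapse = ", ")),
          class = "format_error")
  }
  reads[need]
}

#' @rdname read_tagged_reads
#' @param reads A tibble of tagged reads.
#' @export
write_tagged_reads <- function(reads, path) {
  readr::write_tsv(reads[c("barcode", "umi", "gene", "species")], path)
  invisible(path)
}
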