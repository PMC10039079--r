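#' Sparse gene-by-barcode count matrix with metadata
#'
#' The central container of the pipeline: deduplicated transcript (UMI) counts
#' per gene and barcode, a feature table carrying the species label and the
#' mitochondrial flag of every gene, and the raw (pre-deduplication) read count
#' of every barcode, which is what depth targets are expressed in.
#'
#' @param counts A genes-by-barcodes matrix of non-negative integer counts
#'   (anything coercible to a `dgCMatrix`). Rownames are gene ids, colnames
#'   barcodes; if absent they are taken from `features` and `barcodes`.
#' @param features A data frame with columns `gene_id`, `species`, `mito`
#'   (one row per matrix row). See [feature_table()].
#' @param barcodes Character vector of barcode identifiers (one per column).
#' @param raw_reads Numeric vector of raw read counts per barcode, same order
#'   as `barcodes`. Defaults to the column totals (appropriate when counts are
#'   generated directly at the transcript level).
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, features, barcodes = colnames(counts),
                         raw_reads = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  features <- validate_features(features)
  if (nrow(counts) != nrow(features)) {
    abort(sprintf("matrix has %d rows but feature table %d",
                  nrow(counts), nrow(features)),
          class = "format_error")
  }
  if (is.null(barcodes)) {
    abort("barcodes missing: supply `barcodes` or give `counts` colnames",
          class = "format_error")
  }
  barcodes <- as.character(barcodes)
  if (ncol(counts) != length(barcodes)) {
    abort(sprintf("matrix has %d columns but %d barcodes",
                  ncol(counts), length(barcodes)),
          class = "format_error")
  }
  if (anyDuplicated(barcodes)) {
    abort("barcodes must be unique", class = "format_error")
  }
  if (length(counts@x) && min(counts@x) < 0) {
    abort("counts must be non-negative", class = "format_error")
  }
  totals <- Matrix::colSums(counts)
  if (is.null(raw_reads)) raw_reads <- totals
  raw_reads <- as.numeric(raw_reads)
  if (length(raw_reads) != length(barcodes)) {
    abort("raw_reads must have one entry per barcode", class = "format_error")
  }
  if (any(raw_reads + 1e-8 < totals)) {
    abort("raw read count of a barcode cannot be below its transcript total",
          class = "format_error")
  }
  dimnames(counts) <- list(features$gene_id, barcodes)
  structure(
    list(counts = counts, features = features, barcodes = barcodes,
         raw_reads = setNames(raw_reads, barcodes)),
    class = "count_matrix"
  )
}

#' Feature (gene) annotation table
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param species Species label per gene (at most two distinct labels are
#'   supported by the species-QC stage).
#' @param mito Logical: is the gene mitochondrial? Defaults to a `MT-`/`mt-`
#'   gene-id prefix test, the usual naming convention.
#'
#' @return A tibble with columns `gene_id`, `species`, `mito`.
#' @export
feature_table <- function(gene_id, species, mito = grepl("^(MT|mt)-", gene_id)) {
  validate_features(tibble(gene_id = as.character(gene_id),
                           species = as.character(species),
                           mito = as.logical(mito)))
}

validate_features <- function(features) {
  features <- as_tibble(features)
  need <- c("gene_id", "species", "mito")
  if (!all(need %in% names(features))) {
    abort("feature table needs columns gene_id, species, mito",
          class = "format_error")
  }
  if (anyDuplicated(features$gene_id)) {
    abort("gene ids must be unique", class = "format_error")
  }
  features[need]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>\n")
  cat(sprintf("  %d genes x %d barcodes, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat(sprintf("  species: %s; %d mitochondrial genes\n",
              paste(unique(x$features$species), collapse = ", "),
              sum(x$features$mito)))
  cat(sprintf("  transcripts: %s; raw reads: %s\n",
              format(sum(x$counts), big.mark = ","),
              format(sum(x$raw_reads), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by barcode
#'
#' @param m A [count_matrix()].
#' @param barcodes Barcodes to keep (order preserved as given).
#' @param genes Optional gene ids to keep.
#' @return A `count_matrix` restricted to the requested barcodes/genes.
#' @export
subset_count_matrix <- function(m, barcodes = m$barcodes,
                                genes = m$features$gene_id) {
  stopifnot(inherits(m, "count_matrix"))
  missing_bc <- setdiff(barcodes, m$barcodes)
  if (length(missing_bc)) {
    abort(sprintf("unknown barcodes: %s",
                  paste(utils::head(missing_bc, 3), collapse = ", ")),
          class = "consistency_error")
  }
  gi <- match(genes, m$features$gene_id)
  if (anyNA(gi)) abort("unknown gene ids", class = "consistency_error")
  count_matrix(m$counts[gi, barcodes, drop = FALSE],
               m$features[gi, ], barcodes,
               raw_reads = unname(m$raw_reads[barcodes]))
}

#' Per-barcode totals of a count matrix as a tibble
#'
#' @param m A [count_matrix()].
#' @return A tibble with one row per barcode: transcript total, gene count
#'   (nonzero genes), mitochondrial transcripts, and raw reads.
#' @export
barcode_totals <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  cm <- m$counts
  tibble(
    barcode = m$barcodes,
    transcripts = Matrix::colSums(cm),
    genes = Matrix::colSums(cm > 0),
    mito_transcripts = Matrix::colSums(cm[m$features$mito, , drop = FALSE]),
    raw_reads = unname(m$raw_reads)
  )
}
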