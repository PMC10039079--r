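#' Parse a FASTQ read pair into tagged reads
#'
#' Slices the cell barcode and UMI out of R1 according to the fixed read
#' layout and assigns each R2 to a gene by lookup against a transcript
#' catalog: first by exact match of the full R2 against the transcript 5'
#' end, then by a `k`-base prefix (default 31). Unmatched reads are kept with
#' gene `UNASSIGNED` so they still count towards raw-read depth; reads whose
#' barcode or UMI contains an N are dropped and counted.
#'
#' @param r1,r2 Paths to the R1 and R2 FASTQ files (uncompressed or gzip).
#' @param layout A [read_layout()].
#' @param catalog Named character vector of transcript sequences, names are
#'   gene ids (as produced by [simulate_experiment()]).
#' @param features Feature table mapping gene ids to species labels.
#' @param k Prefix length for the fallback k-mer lookup.
#'
#' @return A tibble of tagged reads (barcode, umi, gene, species) with
#'   attributes `n_input` (records per file) and `n_dropped` (N-containing
#'   reads removed); `n_dropped + nrow = n_input`.
#' @export
parse_fastq_pair <- function(r1, r2, layout = read_layout(), catalog,
                             features, k = 31L) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) {
    abort(sprintf("R1 has %d records but R2 has %d: files out of sync",
                  length(s1), length(s2)),
          class = "synchronization_error")
  }
  if (length(s1) && min(Biostrings::width(s1)) < max(layout$barcode[2],
                                                     layout$umi[2])) {
    abort("R1 shorter than the barcode/UMI layout spans",
          class = "layout_error")
  }
  r1_chr <- unname(as.character(s1))
  bc <- substr(r1_chr, layout$barcode[1], layout$barcode[2])
  umi <- substr(r1_chr, layout$umi[1], layout$umi[2])
  keep <- !grepl("N", bc, fixed = TRUE) & !grepl("N", umi, fixed = TRUE)
  cdna <- unname(as.character(s2))[keep]
  gene <- assign_genes(cdna, catalog, r2_length = layout$r2_length, k = k)
  out <- tibble(
    barcode = bc[keep], umi = umi[keep], gene = gene,
    species = species_of(gene, features)
  )
  attr(out, "n_input") <- length(s1)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Exact 5'-end lookup with a k-mer prefix fallback; a desk-scale stand-in for
# a genome aligner, only meaningful against the bundled transcript catalog.
assign_genes <- function(cdna, catalog, r2_length = 70L, k = 31L) {
  stopifnot(!is.null(names(catalog)))
  full_key <- substr(unname(catalog), 1L, r2_length)
  hit <- match(substr(cdna, 1L, r2_length), full_key)
  miss <- is.na(hit)
  if (any(miss)) {
    pref_key <- substr(unname(catalog), 1L, k)
    hit[miss] <- match(substr(cdna[miss], 1L, k), pref_key)
  }
  if_else(is.na(hit), UNASSIGNED, names(catalog)[hit])
}

species_of <- function(gene, features) {
  sp <- features$species[match(gene, features$gene_id)]
  if_else(gene == UNASSIGNED, UNASSIGNED,
          if_else(is.na(sp), UNASSIGNED, sp))
}

#' Write tagged reads as a FASTQ pair
#'
#' Reconstructs fixed-layout reads: R1 is barcode + UMI padded to the layout
#' length with A, R2 is the transcript 5' end from the catalog. Qualities are
#' written as constant 'I' (Phred 40). Used by the simulator's FASTQ output.
#'
#' @inheritParams parse_fastq_pair
#' @param reads A tibble of tagged reads.
#' @param r1,r2 Output FASTQ paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_fastq_pair <- function(reads, r1, r2, layout = read_layout(), catalog) {
  pad <- layout$r1_length - umi_length(layout) - barcode_length(layout)
  r1_seq <- paste0(reads$barcode, reads$umi,
                   strrep("A", max(pad, 0L)))
  r2_seq <- substr(unname(catalog)[match(reads$gene, names(catalog))],
                   1L, layout$r2_length)
  if (anyNA(r2_seq)) {
    abort("tagged reads reference genes absent from the catalog",
          class = "consistency_error")
  }
  ids <- sprintf("read%d", seq_len(nrow(reads)))
  write_fastq_one(r1_seq, ids, r1)
  write_fastq_one(r2_seq, ids, r2)
  invisible(list(r1 = r1, r2 = r2))
}

write_fastq_one <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
}
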