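# Shared fixture builders: everything is generated in code at test time.

# count matrix with one gene per species; columns given as (a, b) transcript
# pairs, so purity arithmetic is easy to check by hand
toy_two_gene_matrix <- function(a, b, species = c("human", "mouse"),
                                barcodes = sprintf("BC%04d", seq_along(a))) {
  counts <- rbind(a, b)
  colnames(counts) <- barcodes
  count_matrix(counts,
               feature_table(c("geneA", "geneB"), species),
               barcodes)
}

# dense toy matrix from an explicit genes x cells integer matrix
toy_matrix <- function(counts, species = rep("human", nrow(counts)),
                       mito = rep(FALSE, nrow(counts))) {
  gene_id <- sprintf("G%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("BC%04d", seq_len(ncol(counts)))
  count_matrix(counts, feature_table(gene_id, species, mito),
               colnames(counts))
}

# two-plateau barcode count vector: n_cells high-count barcodes over an
# empty-bead background
two_plateau_counts <- function(n_cells = 2000, n_empty = 20000,
                               cell_mean = 1000, empty_mean = 10,
                               seed = 1) {
  withr::with_seed(seed, {
    counts <- c(rpois(n_cells, cell_mean), rpois(n_empty, empty_mean))
    names(counts) <- c(sprintf("CELL%05d", seq_len(n_cells)),
                       sprintf("BEAD%05d", seq_len(n_empty)))
    counts[counts >= 1]
  })
}

# small read-level simulation used by several IO/quantify tests
small_read_sim <- function(seed = 42, ...) {
  simulate_experiment(sim_config(
    n_cells_per_species = c(human = 20, mouse = 20),
    transcripts_per_cell = c(100, 2), genes_per_species = 50,
    reads_per_transcript = 3, seed = seed, ...
  ))
}
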