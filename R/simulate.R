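#' Configuration of a synthetic barnyard experiment
#'
#' Describes a two-species mixture experiment generatively: each cell-bead
#' complex carries one cell of a known species and, with probability
#' `doublet_prob`, a second cell of uniformly random species (the residual
#' failure mode of coupling in bead excess). A fraction `ambient_rate` of
#' every barcode's captured transcripts is drawn from a pooled ambient
#' distribution (lysate crosstalk), whose species composition is proportional
#' to the total cellular transcripts of each species. Optional empty beads
#' capture only ambient material.
#'
#' Defaults are the study conditions used throughout the package's validation:
#' 2,500 complexes per species, 6% second-cell probability (so ~3% of
#' complexes are hetero-species multiplets), 1% ambient contamination, and
#' negative-binomial transcript totals with mean 5,000 and dispersion (size)
#' 2. Expression profiles are per-species symmetric Dirichlet(0.05) draws over
#' `genes_per_species` genes, 3% of which are flagged mitochondrial.
#'
#' @param n_cells_per_species Named integer vector: complexes per species
#'   (names are the species labels).
#' @param doublet_prob Probability a complex carries a second cell.
#' @param ambient_rate Fraction of each barcode's transcripts drawn from the
#'   ambient pool.
#' @param transcripts_per_cell Length-2 numeric `c(mean, dispersion)` of the
#'   negative binomial transcript total per cell (dispersion is the `size`
#'   parameter of [stats::rnbinom()]).
#' @param genes_per_species Genes per species in the catalog.
#' @param mito_fraction Fraction of each species' genes flagged mitochondrial.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet expression
#'   profile.
#' @param reads_per_transcript Poisson mean of PCR/sequencing duplicates per
#'   transcript (read-level generator only; every transcript is seen at least
#'   once). The default 4 corresponds to ~20,000 raw reads per cell at the
#'   default 5,000 transcripts.
#' @param n_empty_beads Number of bead-only barcodes with Poisson(mean
#'   `empty_bead_mean`) ambient transcripts.
#' @param empty_bead_mean Mean ambient transcripts per empty bead.
#' @param umi_length UMI length in bases; collisions over the 4^length space
#'   are allowed (and measurable after deduplication).
#' @param barcode_length Cell-barcode length in bases.
#' @param seed Integer seed; fixed seed makes all outputs deterministic.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_species = c(human = 2500L, mouse = 2500L),
                       doublet_prob = 0.06,
                       ambient_rate = 0.01,
                       transcripts_per_cell = c(mean = 5000, dispersion = 2),
                       genes_per_species = 500L,
                       mito_fraction = 0.03,
                       dirichlet_alpha = 0.05,
                       reads_per_transcript = 4,
                       n_empty_beads = 0L,
                       empty_bead_mean = 20,
                       umi_length = 12L,
                       barcode_length = 16L,
                       seed = 1L) {
  if (is.null(names(n_cells_per_species)) ||
      any(!nzchar(names(n_cells_per_species)))) {
    abort("n_cells_per_species must be a named vector of species labels",
          class = "config_error")
  }
  if (length(n_cells_per_species) != 2L) {
    abort("exactly two species are supported", class = "config_error")
  }
  stopifnot(
    doublet_prob >= 0, doublet_prob <= 1,
    ambient_rate >= 0, ambient_rate <= 1,
    all(n_cells_per_species >= 0), n_empty_beads >= 0,
    transcripts_per_cell[1] > 0, transcripts_per_cell[2] > 0,
    genes_per_species >= 1, mito_fraction >= 0, mito_fraction <= 1
  )
  if (sum(n_cells_per_species) + n_empty_beads == 0) {
    abort("nothing to simulate: no cells and no empty beads",
          class = "config_error")
  }
  structure(
    list(
      n_cells_per_species = n_cells_per_species,
      doublet_prob = doublet_prob,
      ambient_rate = ambient_rate,
      transcripts_per_cell = unname(transcripts_per_cell),
      genes_per_species = as.integer(genes_per_species),
      mito_fraction = mito_fraction,
      dirichlet_alpha = dirichlet_alpha,
      reads_per_transcript = reads_per_transcript,
      n_empty_beads = as.integer(n_empty_beads),
      empty_bead_mean = empty_bead_mean,
      umi_length = as.integer(umi_length),
      barcode_length = as.integer(barcode_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  complexes: %s; doublet prob %.3g; ambient %.3g\n",
              paste(sprintf("%s=%d", names(x$n_cells_per_species),
                            x$n_cells_per_species), collapse = ", "),
              x$doublet_prob, x$ambient_rate))
  cat(sprintf("  transcripts/cell NB(mean %g, size %g); %d genes/species; seed %d\n",
              x$transcripts_per_cell[1], x$transcripts_per_cell[2],
              x$genes_per_species, x$seed))
  invisible(x)
}

random_seqs <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

unique_barcodes <- function(n, len) {
  bc <- random_seqs(n, len)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- random_seqs(sum(dup), len)
  }
  bc
}

# Genes, species labels, mito flags and Dirichlet expression profiles.
sim_genes <- function(cfg) {
  sp <- names(cfg$n_cells_per_species)
  n_mito <- round(cfg$mito_fraction * cfg$genes_per_species)
  per_species <- lapply(sp, function(s) {
    base <- sprintf("%s-G%04d", toupper(s), seq_len(cfg$genes_per_species))
    mito <- seq_len(cfg$genes_per_species) <= n_mito
    tibble(gene_id = if_else(mito, paste0("MT-", base), base),
           species = s, mito = mito)
  })
  features <- bind_rows(per_species)
  profiles <- vapply(sp, function(s) {
    w <- rgamma(cfg$genes_per_species, shape = cfg$dirichlet_alpha)
    w <- w / sum(w)
    p <- numeric(nrow(features))
    p[features$species == s] <- w
    p
  }, numeric(nrow(features)))
  colnames(profiles) <- sp
  list(features = features, profiles = profiles)
}

# Core generative draw shared by the matrix- and read-level generators:
# barcode identities, cell content, transcript totals and per-barcode gene
# counts split into own-cell and ambient provenance.
sim_core <- function(cfg) {
  sp <- names(cfg$n_cells_per_species)
  g <- sim_genes(cfg)
  n_cells <- sum(cfg$n_cells_per_species)
  n_bc <- n_cells + cfg$n_empty_beads
  barcodes <- unique_barcodes(n_bc, cfg$barcode_length)

  species1 <- rep(sp, cfg$n_cells_per_species)
  has_second <- rbinom(n_cells, 1L, cfg$doublet_prob) == 1L
  species2 <- rep(NA_character_, n_cells)
  species2[has_second] <- sample(sp, sum(has_second), replace = TRUE)

  mu <- cfg$transcripts_per_cell[1]
  size <- cfg$transcripts_per_cell[2]
  t1 <- rnbinom(n_cells, size = size, mu = mu)
  t2 <- integer(n_cells)
  t2[has_second] <- rnbinom(sum(has_second), size = size, mu = mu)
  totals <- t1 + t2

  # ambient pool composition: proportional to total cellular transcripts
  sp_tot <- vapply(sp, function(s) {
    sum(t1[species1 == s]) + sum(t2[has_second][species2[has_second] == s])
  }, numeric(1))
  pool <- as.numeric(g$profiles %*% (sp_tot / sum(sp_tot)))

  # per-barcode own-cell profile: singlets use their species profile,
  # doublets an equal-weight mixture of both member cells' profiles
  own_profile <- function(i) {
    if (!has_second[i]) return(g$profiles[, species1[i]])
    (g$profiles[, species1[i]] + g$profiles[, species2[i]]) / 2
  }

  n_genes <- nrow(g$features)
  counts <- matrix(0L, nrow = n_genes, ncol = n_bc)
  ambient_n <- integer(n_bc)
  for (i in seq_len(n_cells)) {
    if (totals[i] == 0L) next
    n_amb <- rbinom(1L, totals[i], cfg$ambient_rate)
    ambient_n[i] <- n_amb
    col <- rmultinom(1L, totals[i] - n_amb, own_profile(i))[, 1]
    if (n_amb > 0L) col <- col + rmultinom(1L, n_amb, pool)[, 1]
    counts[, i] <- col
  }
  if (cfg$n_empty_beads > 0L) {
    t_empty <- rpois(cfg$n_empty_beads, cfg$empty_bead_mean)
    for (j in seq_len(cfg$n_empty_beads)) {
      i <- n_cells + j
      ambient_n[i] <- t_empty[j]
      if (t_empty[j] > 0L) counts[, i] <- rmultinom(1L, t_empty[j], pool)[, 1]
    }
  }

  content <- c(if_else(has_second, "doublet", "singlet"),
               rep("none", cfg$n_empty_beads))
  hetero <- has_second & !is.na(species2) & species1 != species2
  truth <- tibble(
    barcode = barcodes,
    content = content,
    species1 = c(species1, rep(NA_character_, cfg$n_empty_beads)),
    species2 = c(species2, rep(NA_character_, cfg$n_empty_beads)),
    is_hetero_doublet = c(hetero, rep(FALSE, cfg$n_empty_beads)),
    transcripts = Matrix::colSums(counts),
    ambient_transcripts = ambient_n
  )
  list(counts = counts, truth = truth, features = g$features,
       barcodes = barcodes)
}

#' Simulate a deduplicated barnyard count matrix
#'
#' Draws a synthetic experiment directly at the transcript level, bypassing
#' reads: the output equals what the read-level pipeline produces at zero
#' sequencing error, up to UMI-collision losses.
#'
#' @param cfg A [sim_config()].
#' @return A list with `matrix` (a [count_matrix()]) and `truth` (a tibble of
#'   per-barcode ground truth: content class, member species, hetero-doublet
#'   flag, transcript and ambient-transcript totals).
#' @examples
#' sim <- simulate_count_matrix(sim_config(
#'   n_cells_per_species = c(human = 50, mouse = 50),
#'   transcripts_per_cell = c(500, 2), seed = 7
#' ))
#' sim$matrix
#' @export
simulate_count_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    core <- sim_core(cfg)
    m <- count_matrix(core$counts, core$features, core$barcodes)
    list(matrix = m, truth = core$truth)
  })
}

#' Simulate a barnyard experiment at the read level
#'
#' Extends the transcript-level generative model down to sequencing reads:
#' every transcript gets a uniformly random UMI (collisions over the 4^12
#' space allowed) and Poisson(`reads_per_transcript`) duplicate reads, at
#' least one. No sequencing errors are introduced, so parsing the output
#' recovers the generative (barcode, UMI, gene) of every read exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list with `reads` (tibble of tagged reads in randomized order),
#'   `truth`, `features`, and `catalog` (named character vector of random
#'   transcript sequences, one per gene, for FASTQ emission and gene lookup).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    core <- sim_core(cfg)
    n_genes <- nrow(core$features)
    catalog <- setNames(random_seqs(n_genes, 500L), core$features$gene_id)

    nz <- which(core$counts != 0, arr.ind = TRUE)
    tx_gene <- rep(nz[, 1], core$counts[nz])
    tx_bc <- rep(nz[, 2], core$counts[nz])
    n_tx <- length(tx_gene)
    umis <- random_seqs(n_tx, cfg$umi_length)
    dup <- pmax(1L, rpois(n_tx, cfg$reads_per_transcript))

    reads <- tibble(
      barcode = rep(core$barcodes[tx_bc], dup),
      umi = rep(umis, dup),
      gene = rep(core$features$gene_id[tx_gene], dup),
      species = rep(core$features$species[tx_gene], dup)
    )
    reads <- reads[sample.int(nrow(reads)), ]
    truth <- core$truth
    truth$reads_emitted <- as.numeric(
      tapply(dup, factor(core$barcodes[tx_bc], levels = core$barcodes), sum,
             default = 0)
    )
    list(reads = reads, truth = truth, features = core$features,
         catalog = catalog)
  })
}
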