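---
title: "Methods: barnyard QC statistics, the knee method, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barnyard QC statistics, the knee method, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barnyardqc)
```

`barnyardqc` implements the quality-control statistics used to validate
bead-based single-cell RNA-seq sample preparation with a two-species
("barnyard") mixture, together with the pre- and post-processing steps those
statistics sit inside: barcode/UMI extraction from fixed-layout read pairs,
knee-based cell calling, UMI deduplication, raw-read downsampling, cell/gene
filtering and log normalization, and experiment-design calculators for
bead-cell coupling yields. This vignette explains the models and the choices
behind them; the README shows the workflow.

## The purity statistic and multiplet rates

In a barnyard experiment, cells of two species (here labelled human and
mouse) are mixed in equal numbers. A bead that captured a single cell sees
almost only transcripts of that cell's species; a bead that captured one cell
of each species sees a mixture. For a barcode with transcript counts $a$ and
$b$ in the two species, let

$$ r = \frac{\min(a, b)}{a + b} $$

be the minority-species fraction. The **cell barcode purity** is defined as

$$ \text{purity} = 1 - 2r. $$

The factor 2 comes from the interpretation of purity as the probability that
a captured transcript was expressed by the barcode's main cell: with equal
total transcripts per species, contaminating material (ambient RNA, or a
second cell) is split roughly evenly between the two species, so the
cross-species minority count is only half of the contamination — the
same-species half is invisible.

Classification uses two thresholds that partition $[0, 1]$ into three
classes:

* purity $\geq 0.95$: the barcode is **assigned** to its majority species;
* purity $< 2/3$ (strictly): the barcode is a **hetero-species multiplet**
  (equivalently, impurity $> 1/3$);
* in between: **undefined** — neither confidently single-species nor a
  detected multiplet.

A barcode at exactly $2/3$ is *not* a multiplet and one at exactly $0.95$
*is* assigned; `purity_table()` follows these boundary conventions exactly,
and a brute-force oracle test checks the formula for every count pair with
$a + b \leq 50$.

Homo-species multiplets (two cells of the same species on one bead) are
invisible to the purity statistic. Under equal species proportions the second
cell is of the other species with probability $1/2$, so the **total**
multiplet rate is extrapolated as twice the measured hetero-species rate.
For unequal designs no extrapolation formula is reported —
`summarize_species(equal_proportions = FALSE)` returns the hetero rate only,
with a note, rather than inventing a correction.

All class percentages (assigned per species, undefined) are computed on one
common denominator, the analyzed barcodes. Reports that use per-class
denominators can exceed 100% when summed; this package does not.

## Cell calling: the distance-based knee

Sorting barcodes by descending read count produces a curve with two plateaus:
cell-associated barcodes and the empty-bead background. `call_cells()` finds
the knee as the point of maximum perpendicular distance to the chord joining
the first and last points of the curve, on one of two parameterizations:

* **`cumulative`** (the default): the cumulative count fraction against the
  barcode-rank fraction. The slope of this curve at rank $r$ is proportional
  to the count of barcode $r$, so the chord distance is maximized exactly
  where per-barcode counts fall through the overall mean count — the edge of
  the cell plateau. On a two-plateau curve this calls essentially the whole
  cell plateau (recall ~100% with ~0% background contamination in the
  package's tests). A background of identical counts makes the curve the
  exact diagonal, which is reported as a no-knee error.
* **`loglog`**: maximum chord distance on the log10(rank)–log10(count)
  curve, with optional moving-average smoothing of the log-count axis
  (window 15 ranks by default). This is the more conservative geometry: the
  maximum-distance point lies at the *shoulder* where the plateau begins to
  bend (where the local slope equals the chord slope), so the lower tail of
  the cell count distribution falls below the threshold. In simulations with
  Poisson(1000) cells over a Poisson(10) background this recovers about 98%
  of cells. An exact power law is a straight line on these axes and is
  reported as knee-free.

The cumulative formulation is the default because it is the behavior
expected of distance-based knee callers on barcode rank data and because the
shoulder bias of the log-log chord systematically under-calls the dimmest
true cells. Both share the same calling rule: the count at the knee is the
threshold; barcodes strictly above it are called, plus barcodes equal to it
up to the knee rank (ties broken towards smaller rank, the conservative
side). Calling is scale-invariant: multiplying every count by a constant
scales the threshold and leaves the called set unchanged.

`manual_threshold()` is the fallback when the expected cell number is known
externally, e.g. from microscope counts of cell-bead complexes.

Whether the rank curve should use raw reads or deduplicated transcripts is a
genuinely open choice; the package defaults to raw reads because cell
detection precedes deduplication in the pipeline's stage ordering, but any
named count vector can be supplied.

## Read layout, gene assignment, deduplication

The default `read_layout()` is a 30-base R1 / 70-base R2 recipe with a
16-base cell barcode at R1 positions 1–16 and a 12-base UMI at 17–28; the
last two R1 bases are ignored. The internal split of R1 is configurable
because bead designs differ; 16+12 mirrors prevalent bead chemistries.
Reads whose barcode or UMI contains an N are dropped (and counted) rather
than error-corrected; no barcode whitelist or correction procedure is
applied.

Gene assignment is an exact lookup of the R2 sequence against the 5' ends of
a transcript catalog, with a 31-base prefix fallback. This is a deliberate
desk-scale stand-in for a genome aligner: it is only meaningful against the
synthetic catalog bundled by the simulator, and real data should be aligned
with a real aligner before entering the pipeline as tagged reads
(`read_tagged_reads()`).

Deduplication collapses reads by exact `(barcode, UMI, gene)` equality; no
UMI error-collapsing network is applied. With UMIs uniform over $4^{12}$,
two transcripts of the same gene in the same cell collide with probability
$4^{-12}$, so a cell with $n$ transcripts of one gene loses
$\binom{n}{2} 4^{-12}$ transcripts in expectation — the package's tests
verify this birthday-problem deficit within $3\sigma$ at $n = 20{,}000$.
Unassigned reads count toward a barcode's raw-read depth (depth targets are
"raw reads per cell") but never toward transcripts.

## Downsampling and tube splitting

`downsample_reads()` thins every read independently with probability
$p = \text{target depth} \times n_\text{cells} / \text{total raw reads}$,
where the total counts reads belonging to called barcodes; the retained
total then has the target expectation. Thinning is unbiased, so species
proportions are unchanged in expectation. Data already below the target
passes through with a warning.

`split_tubes()` assigns barcodes (i.e. beads, the physical unit that is
split) to tubes uniformly at random. Tubes partition the matrix exactly, and
per-tube quality indicators on simulated data agree within 10%, mirroring
the inter-tube repeatability expected of a well-mixed bead suspension.

## Filters and normalization

`filter_matrix()` applies, in order: genes expressed in fewer than 3 cells
are dropped; cells with fewer than 200 genes (counted on remaining genes)
are dropped; cells with a mitochondrial transcript rate above 20% (computed
on remaining genes) are dropped. Because removing cells can push a gene back
under the first rule, the pass is repeated until nothing changes; the fixed
point makes filtering idempotent, and the filter report accumulates per-rule
drop counts across passes. Mitochondrial genes are identified by the feature
table's flag, or by the conventional `MT-`/`mt-` gene-name prefix.

Normalization is
$$ \log_2(10{,}000 \cdot X + 1), $$
where $X$ is the *fraction* of the cell's transcripts on the gene. The
fraction reading (rather than a 0–100 percentage) keeps the $10^4$
multiplier's counts-per-ten-thousand meaning: a gene carrying 1% of a cell's
transcripts maps to $\log_2(101) \approx 6.658$ regardless of sequencing
depth, and a cell concentrated on one gene to
$\log_2(10{,}001) \approx 13.288$. Zeros map to zeros, so sparsity is
preserved, and each cell's normalized vector is invariant to scaling its
counts.

## The synthetic barnyard generator

`sim_config()` describes an experiment generatively; its defaults are the
package's reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_cells_per_species` | 2,500 + 2,500 | cell-bead complexes per species |
| `doublet_prob` | 0.06 | probability a complex carries a second cell |
| `ambient_rate` | 0.01 | fraction of captured transcripts from the ambient pool |
| `transcripts_per_cell` | NB(5000, 2) | negative binomial (mean, size) |
| `genes_per_species` | 500 | catalog size per species |
| `mito_fraction` | 0.03 | genes flagged mitochondrial |
| `dirichlet_alpha` | 0.05 | symmetric Dirichlet expression concentration |
| `reads_per_transcript` | 4 | Poisson duplicate mean (read level) |
| `n_empty_beads` | 0 | bead-only barcodes, Poisson(20) ambient transcripts |

The second cell of a doublet is of uniformly random species, so a fraction
`doublet_prob`/2 of complexes are hetero-species; at the defaults that is
3%, and the species-QC stage recovers it. Complexes never carry more than
two cells — beads are in large excess over cells precisely so that
multi-cell capture is the residual failure mode, and the two-cell case is
what the purity statistic measures. The ambient pool is a mass-action model
of lysate crosstalk: its species composition is proportional to each
species' total cellular transcripts, and each barcode replaces a
`Binomial(total, ambient_rate)` share of its transcripts with ambient draws.
Doublet barcodes draw their own-cell transcripts from an equal-weight
mixture of both member cells' species profiles. Empty beads default to zero
because purity analyses operate on cell-associated barcodes; they are
switched on to exercise the cell-calling stage, where they form the
background plateau.

With `ambient_rate = 0.01` and a balanced pool, a singlet's expected
cross-species fraction is $\approx 0.005$, purity $\approx 0.99$ — far from
the $2/3$ multiplet boundary — while a hetero doublet sits near purity 0, so
the measured hetero rate is an essentially unbiased estimate of the
generative rate. The 1% ambient default is a plausible placeholder for
lysate crosstalk in a well-spaced gel, not a measured value.

The read-level generator (`simulate_experiment()`) assigns each transcript a
uniform 12-base UMI and Poisson(4) duplicate reads (minimum one; the default
corresponds to ~20,000 raw reads per cell at 5,000 transcripts), emits
tagged reads in randomized order, and can be written to FASTQ with constant
'I' qualities. No sequencing errors are introduced, so parsing recovers the
generative record of every read exactly — which is what makes the parser and
deduplicator testable end to end. The matrix-level generator
(`simulate_count_matrix()`) bypasses reads and emits deduplicated counts
directly; it equals the read-level path up to UMI collisions.

What the generator does *not* emulate: realistic transcript sequences (the
catalog is random 500-mers), sequencing errors and quality-score structure,
chimeric PCR artifacts, gene-length or GC biases, and realistic per-cell
gene diversity — the Dirichlet(0.05) profiles concentrate a cell's
transcripts on a few dozen effective genes, far fewer than a real cell
expresses. Passing tests therefore validate the statistics and their
implementations under a known generative model, not the behavior of any
particular wet-lab protocol on real tissue; in particular the 200-genes-
per-cell filter default, sensible for real data, removes almost everything
simulated at these profile concentrations, so simulation-driven tests use
smaller thresholds.

## Experiment-design calculators

`expected_cells_in_data()` multiplies microscope-counted cell-bead complexes
by the bead recovery rate of the sequenced tube(s); with the bead suspension
split into 8 PCR tubes, per-tube recovery cannot exceed 12.5%.
`tube_fraction()` divides input cells by tubes (10,000 cells over 8 tubes =
1,250 per tube). `mean_complex_spacing()` reports two spacing notions for
$n$ complexes in volume $V$: the cube-root lattice spacing $(V/n)^{1/3}$
(584.8 µm for 10,000 cells in 2 mL) and the mean nearest-neighbor distance
of a homogeneous Poisson process, $0.5539\,(V/n)^{1/3}$ (323.9 µm). Both are
reported because "average distance between cells" is ambiguous between them;
neither is privileged. Estimates are point values — propagation of
microscope counting error is out of scope.

## Numerical and testing notes

* Every stochastic operation takes an explicit seed and is exactly
  reproducible; the full pipeline writes byte-identical reports under a
  fixed seed.
* Boundary semantics: purity thresholds are evaluated on the computed
  double-precision value; the bundled tests pin the exact-2/3 and
  exact-0.95 cases.
* Knee detection requires at least 100 nonzero barcodes and declares a
  no-knee error when the maximum chord distance is below $10^{-6}$.
* Test problem sizes: simulation-backed checks use 40–5,000 complexes per
  run and 10 replicate seeds for rate-recovery checks (binomial 3-SE
  bands); the knee performance check uses 5,000 cells over 100,000 empty
  beads. These sizes keep every statistical band tight enough to detect
  implementation errors while the whole suite stays fast.
* Downstream analysis (HVG selection, PCA, embedding, clustering,
  differential expression, cell-type annotation) is deliberately out of
  scope: the filtered, normalized matrix is written in standard Matrix
  Market exchange format for the established tools that do those steps.

## A worked example

```{r example}
sim <- simulate_count_matrix(sim_config(
  n_cells_per_species = c(human = 300, mouse = 300),
  transcripts_per_cell = c(1000, 2), seed = 7
))
purity <- purity_table(sim$matrix)
glance(summarize_species(purity))
```

```{r barnyard-plot, fig.width = 5, fig.height = 4}
autoplot(purity)
```
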