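#' Bead-yield model: expected cells in sequencing data
#'
#' The number of cells expected in sequencing data is the product of the
#' microscope-counted cell-bead complexes and the bead recovery rate of the
#' sequenced tubes. Since the bead suspension is split into `n_tubes` PCR
#' tubes, the recovery rate of a single tube cannot exceed `1 / n_tubes`
#' (12.5% for the standard 8-tube split).
#'
#' @param n_complexes Microscope-counted cell-bead complexes in the sample.
#' @param bead_recovery_rate Recovered-bead fraction per sequenced tube
#'   (recycled to length `n_tubes_sequenced`).
#' @param n_tubes Total PCR tubes the sample was split into.
#' @param n_tubes_sequenced How many of those tubes were sequenced.
#' @return `bead_yield_model()`: an object of class `bead_yield_model`.
#'   `expected_cells_in_data()`: a one-row tibble with the estimate (rounded
#'   to the nearest cell) and the inputs echoed for audit.
#' @examples
#' expected_cells_in_data(bead_yield_model(10000, 0.06))
#' @export
bead_yield_model <- function(n_complexes, bead_recovery_rate,
                             n_tubes = 8L, n_tubes_sequenced = 1L) {
  stopifnot(n_complexes >= 0, n_tubes >= 1,
            n_tubes_sequenced >= 1, n_tubes_sequenced <= n_tubes)
  rate <- rep_len(bead_recovery_rate, n_tubes_sequenced)
  if (any(rate < 0) || any(rate > 1 / n_tubes + 1e-12)) {
    abort(sprintf(
      "per-tube bead recovery rate must lie in [0, %.4g] for a %d-tube split",
      1 / n_tubes, n_tubes), class = "validation_error")
  }
  structure(
    list(n_complexes = n_complexes, bead_recovery_rate = rate,
         n_tubes = as.integer(n_tubes),
         n_tubes_sequenced = as.integer(n_tubes_sequenced)),
    class = "bead_yield_model"
  )
}

#' @rdname bead_yield_model
#' @param model A `bead_yield_model`.
#' @export
expected_cells_in_data <- function(model) {
  stopifnot(inherits(model, "bead_yield_model"))
  est <- model$n_complexes * sum(model$bead_recovery_rate)
  tibble(
    expected_cells = round(est),
    n_complexes = model$n_complexes,
    total_recovery_rate = sum(model$bead_recovery_rate),
    n_tubes_sequenced = model$n_tubes_sequenced
  )
}

#' Input cells represented by each PCR tube
#'
#' Splitting the bead suspension into `n_tubes` PCR tubes is equivalent to
#' splitting the input cells into that many sub-fractions, so each tube
#' represents `input_cells / n_tubes` cells (e.g. 1,250 of 10,000 input cells
#' for the standard 8-tube split).
#'
#' @param input_cells Number of input cells in the sample.
#' @param n_tubes Number of PCR tubes.
#' @return A one-row tibble: exact cells per tube plus floor and ceiling.
#' @export
tube_fraction <- function(input_cells, n_tubes = 8L) {
  stopifnot(input_cells >= 0, n_tubes >= 1)
  per <- input_cells / n_tubes
  tibble(cells_per_tube = per, floor = floor(per), ceiling = ceiling(per))
}

#' Mean spacing between cell-bead complexes in the hydrogel
#'
#' For `n` complexes dispersed in a gel volume `V`, two spacing notions:
#' `cube_root` is the lattice spacing `(V/n)^(1/3)`, and `poisson_nn` the mean
#' nearest-neighbor distance of a homogeneous Poisson point process,
#' `0.5539 * (n/V)^(-1/3)`. Both are returned in micrometres. Large spacing
#' relative to the lysate diffusion scale is what keeps cross-bead crosstalk
#' low.
#'
#' @param n_cells Number of complexes.
#' @param gel_volume_ml Gel volume in millilitres.
#' @param estimator `"cube_root"`, `"poisson_nn"`, or `"both"`.
#' @return A tibble with columns estimator and spacing_um.
#' @examples
#' mean_complex_spacing(10000, 2)
#' @export
mean_complex_spacing <- function(n_cells, gel_volume_ml,
                                 estimator = c("both", "cube_root",
                                               "poisson_nn")) {
  estimator <- match.arg(estimator)
  stopifnot(n_cells > 0, gel_volume_ml > 0)
  vol_um3 <- gel_volume_ml * 1e12  # 1 mL = 1e12 um^3
  cube <- (vol_um3 / n_cells)^(1 / 3)
  out <- tibble(
    estimator = c("cube_root", "poisson_nn"),
    spacing_um = c(cube, 0.5539 * cube)
  )
  if (estimator != "both") out <- filter(out, .data$estimator == !!estimator)
  out
}
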