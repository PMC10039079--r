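#' Per-barcode species purity table
#'
#' For every barcode of a two-species experiment, splits its transcripts by
#' species and computes the cell barcode purity: with `minority_ratio` the
#' fraction of transcripts belonging to the minority species,
#' `impurity = 2 * minority_ratio` and `purity = 1 - impurity`. The factor 2
#' reflects that, under an equal split of ambient material between the two
#' species, cross-species transcripts are only half of the contaminating
#' material — the same-species half is invisible.
#'
#' Classification thresholds: a barcode is assigned to its majority species
#' when purity >= 0.95 ("undefined" otherwise), and flagged as a
#' hetero-species multiplet when purity < 2/3 (strictly; a barcode at exactly
#' 2/3 is not a multiplet).
#'
#' @param m A [count_matrix()] whose feature table declares exactly two
#'   species.
#' @return A tibble of class `purity_table`, one row per barcode with >= 1
#'   transcript: per-species transcript counts, minority_ratio, impurity,
#'   purity, assignment (species label or `"undefined"`), and
#'   `is_hetero_multiplet`. Zero-transcript barcodes are excluded with a
#'   warning; the number excluded is in attribute `n_zero_excluded`.
#' @examples
#' m <- count_matrix(
#'   Matrix::Matrix(c(100, 0, 75, 25, 50, 50), nrow = 2,
#'                  dimnames = list(NULL, c("b1", "b2", "b3"))),
#'   feature_table(c("hA", "mB"), c("human", "mouse"))
#' )
#' purity_table(m)
#' @export
purity_table <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  species <- unique(m$features$species)
  if (length(species) != 2L) {
    abort(sprintf(
      "species QC requires exactly 2 species in the feature table, found %d (%s)",
      length(species), paste(species, collapse = ", ")),
      class = "unsupported_design_error")
  }
  species <- sort(species)
  a <- Matrix::colSums(m$counts[m$features$species == species[1], ,
                                drop = FALSE])
  b <- Matrix::colSums(m$counts[m$features$species == species[2], ,
                                drop = FALSE])
  zero <- a + b == 0
  if (any(zero)) {
    warn(sprintf("%d barcode(s) with 0 transcripts excluded from purity table",
                 sum(zero)))
  }
  a <- a[!zero]
  b <- b[!zero]
  out <- tibble(
    barcode = m$barcodes[!zero],
    count_a = unname(a),
    count_b = unname(b)
  ) |>
    mutate(
      minority_ratio = pmin(.data$count_a, .data$count_b) /
        (.data$count_a + .data$count_b),
      impurity = 2 * .data$minority_ratio,
      purity = 1 - .data$impurity,
      assignment = dplyr::case_when(
        purity < 0.95 ~ "undefined",
        count_a >= count_b ~ species[1],
        TRUE ~ species[2]
      ),
      is_hetero_multiplet = .data$purity < 2 / 3
    )
  attr(out, "species") <- species
  attr(out, "n_zero_excluded") <- sum(zero)
  class(out) <- c("purity_table", class(out))
  out
}

#' Experiment-level species summary
#'
#' Aggregates a purity table into the rates reported for a barnyard
#' experiment: the proportion of barcodes assigned to each species and left
#' undefined (one common denominator, all analyzed barcodes), the measured
#' hetero-species multiplet rate (purity < 2/3), and — for equal-proportion
#' designs — the extrapolated total multiplet rate, twice the hetero rate,
#' because a multiplet is hetero-species with probability 1/2 when the two
#' species are mixed in equal numbers and homo-species multiplets are
#' invisible to the purity statistic.
#'
#' @param records A `purity_table` from [purity_table()].
#' @param equal_proportions Were the species mixed in equal cell numbers? If
#'   `FALSE`, no extrapolation formula applies and the total rate is `NA`
#'   with an explanatory note.
#' @return A one-row tibble of class `species_summary`: n_barcodes,
#'   percentage per assignment class, `hetero_multiplet_rate` and
#'   `total_multiplet_rate` (both in percent), and the species balance (share
#'   of total transcripts per species).
#' @export
summarize_species <- function(records, equal_proportions = TRUE) {
  stopifnot(inherits(records, "purity_table"), nrow(records) >= 1)
  species <- attr(records, "species")
  n <- nrow(records)
  hetero <- 100 * sum(records$is_hetero_multiplet) / n
  total <- if (equal_proportions) 2 * hetero else NA_real_
  out <- tibble(
    n_barcodes = n,
    pct_species_a = 100 * sum(records$assignment == species[1]) / n,
    pct_species_b = 100 * sum(records$assignment == species[2]) / n,
    pct_undefined = 100 * sum(records$assignment == "undefined") / n,
    hetero_multiplet_rate = hetero,
    total_multiplet_rate = total,
    balance_a = sum(records$count_a) /
      sum(records$count_a + records$count_b),
    balance_b = sum(records$count_b) /
      sum(records$count_a + records$count_b)
  )
  attr(out, "species") <- species
  attr(out, "equal_proportions") <- equal_proportions
  if (!equal_proportions) {
    attr(out, "note") <- paste(
      "total multiplet rate omitted: the x2 extrapolation from the",
      "hetero-species rate only holds for equal species proportions")
  }
  class(out) <- c("species_summary", class(out))
  out
}

#' @describeIn summarize_species `glance()` returns the summary as a plain
#'   one-row tibble.
#' @param x A `species_summary`.
#' @param ... Unused.
#' @method glance species_summary
#' @export
glance.species_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "species_summary")
  out
}

#' Barnyard plot data
#'
#' One row per barcode with its transcript count in each species and the
#' plotting class: the assigned species for purity >= 95%, `"undefined"`
#' (conventionally drawn gray) below.
#'
#' @param records A `purity_table`.
#' @return A tibble with columns barcode, the two per-species counts (named
#'   after the species), and class.
#' @export
barnyard_plot_data <- function(records) {
  stopifnot(inherits(records, "purity_table"))
  species <- attr(records, "species")
  out <- tibble(
    barcode = records$barcode,
    x = records$count_a,
    y = records$count_b,
    class = records$assignment
  )
  names(out)[2:3] <- species
  out
}

#' Barnyard plot
#'
#' @param object A `purity_table`.
#' @param ... Unused.
#' @return A ggplot of per-barcode transcript counts of one species against
#'   the other, colored by assignment (undefined barcodes in gray).
#' @method autoplot purity_table
#' @export
autoplot.purity_table <- function(object, ...) {
  species <- attr(object, "species")
  df <- barnyard_plot_data(object)
  names(df)[2:3] <- c("x", "y")
  cols <- setNames(c("#e08214", "#35978f", "grey60"),
                   c(species, "undefined"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::labs(x = sprintf("%s transcripts", species[1]),
                  y = sprintf("%s transcripts", species[2]),
                  color = NULL) +
    ggplot2::theme_minimal()
}
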