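#' Barcode rank curve
#'
#' Barcodes sorted by descending count with log10 transforms of both axes;
#' the two plateaus of the curve separate cell-associated barcodes from
#' empty-bead background.
#'
#' @param counts Named numeric vector (barcode -> count) or a two-column data
#'   frame (barcode, count). Zero-count barcodes are excluded.
#' @return A tibble with columns barcode, count, rank, log_rank, log_count,
#'   ordered by rank. Ties in count are ordered lexicographically by barcode
#'   so the curve is deterministic.
#' @export
rank_curve <- function(counts) {
  counts <- as_barcode_counts(counts)
  counts <- counts[counts$count >= 1, ]
  counts <- arrange(counts, desc(.data$count), .data$barcode)
  mutate(counts,
         rank = row_number(),
         log_rank = log10(.data$rank),
         log_count = log10(.data$count))
}

as_barcode_counts <- function(counts) {
  if (is.data.frame(counts)) {
    df <- as_tibble(counts)
    if (!all(c("barcode", "count") %in% names(df))) {
      names(df)[1:2] <- c("barcode", "count")
    }
    tibble(barcode = as.character(df$barcode), count = as.numeric(df$count))
  } else {
    if (is.null(names(counts))) {
      abort("counts must be a named vector or a (barcode, count) data frame",
            class = "format_error")
    }
    tibble(barcode = names(counts), count = as.numeric(counts))
  }
}

#' Detect cell-associated barcodes with a distance-based knee method
#'
#' The knee of the barcode rank curve is found as the point of maximum
#' perpendicular distance to the chord joining the curve's first and last
#' points, on one of two parameterizations:
#'
#' * `"cumulative"` (default): the curve of cumulative count fraction against
#'   barcode-rank fraction. Its slope at rank r is proportional to the count
#'   of barcode r, so the distance to the chord is maximized exactly where
#'   per-barcode counts drop through the overall mean — the edge of the cell
#'   plateau. A background of identical counts makes this curve the exact
#'   diagonal, which is reported as knee-free.
#' * `"loglog"`: the log10(rank) versus log10(count) curve, the log-count
#'   axis optionally moving-average smoothed. This variant places the knee at
#'   the shoulder where the plateau starts bending (where the local slope
#'   equals the chord slope), which is more conservative: the lower tail of
#'   the cell count distribution falls below its threshold. An exact power
#'   law is a straight line here and is reported as knee-free.
#'
#' Ties are broken towards the smaller rank. The count at the knee becomes
#' the threshold: every barcode with a strictly greater count is called, plus
#' barcodes equal to the threshold up to the knee rank.
#'
#' @param counts Named numeric vector (barcode -> count) or a (barcode, count)
#'   data frame, typically raw read counts per barcode.
#' @param method Curve parameterization, see above.
#' @param smoothing_window Moving-average window (in ranks) applied to the
#'   log-count axis of the `"loglog"` curve before measuring distances; 1
#'   disables smoothing. Ignored by `"cumulative"`.
#' @param tol Curves whose maximum chord distance is below `tol` are declared
#'   knee-free.
#' @return An object of class `cell_call` with the knee rank, the count
#'   threshold, the set of called barcodes, and the diagnostic curve.
#' @seealso [manual_threshold()] for calling a fixed number of barcodes,
#'   [autoplot.cell_call()] for the diagnostic plot.
#' @examples
#' set.seed(1)
#' counts <- c(rpois(500, 1000), rpois(5000, 10))
#' names(counts) <- sprintf("BC%05d", seq_along(counts))
#' call_cells(counts)
#' @export
call_cells <- function(counts, method = c("cumulative", "loglog"),
                       smoothing_window = 15L, tol = 1e-6) {
  method <- match.arg(method)
  curve <- rank_curve(counts)
  if (nrow(curve) < 100) {
    abort(sprintf(
      "only %d barcodes with count >= 1; at least 100 are required for knee detection",
      nrow(curve)), class = "insufficient_data_error")
  }
  if (method == "cumulative") {
    x <- curve$rank / nrow(curve)
    y <- cumsum(curve$count) / sum(curve$count)
  } else {
    x <- curve$log_rank
    y <- curve$log_count
    if (smoothing_window > 1) y <- moving_average(y, smoothing_window)
  }
  d <- chord_distance(x, y)
  if (max(d) < tol) {
    abort(paste("no knee: the rank curve has no bend on this scale;",
                "use manual_threshold() with an expected cell count"),
          class = "no_knee_error")
  }
  knee <- which.max(d)  # which.max takes the first maximum: smaller rank
  threshold <- curve$count[knee]
  called <- curve$barcode[curve$count > threshold |
                            (curve$count == threshold &
                               curve$rank <= knee)]
  structure(
    list(knee_rank = knee, threshold = threshold, barcodes = called,
         curve = mutate(curve, distance = d, called = .data$barcode %in% called),
         method = method, smoothing_window = smoothing_window),
    class = "cell_call"
  )
}

moving_average <- function(y, window) {
  half <- (window - 1) %/% 2
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# perpendicular distance of each point to the chord from first to last point
chord_distance <- function(x, y) {
  n <- length(x)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(rep(0, n))
  abs(dx * (y[1] - y) - dy * (x[1] - x)) / len
}

#' Call a fixed number of top barcodes
#'
#' Fallback for samples where the expected cell number is known externally
#' (e.g. from microscope counts of cell-bead complexes): the top
#' `n_expected_cells` barcodes by count are called, ties at the boundary
#' broken lexicographically by barcode.
#'
#' @inheritParams call_cells
#' @param n_expected_cells Number of barcodes to call.
#' @return An object of class `cell_call`.
#' @export
manual_threshold <- function(counts, n_expected_cells) {
  stopifnot(n_expected_cells >= 1)
  curve <- rank_curve(counts)
  if (n_expected_cells > nrow(curve)) {
    abort(sprintf("asked for %d cells but only %d barcodes have counts",
                  n_expected_cells, nrow(curve)),
          class = "insufficient_data_error")
  }
  called <- curve$barcode[seq_len(n_expected_cells)]
  structure(
    list(knee_rank = as.integer(n_expected_cells),
         threshold = curve$count[n_expected_cells], barcodes = called,
         curve = mutate(curve, distance = NA_real_,
                        called = .data$barcode %in% called),
         method = "manual", smoothing_window = NA_integer_),
    class = "cell_call"
  )
}

#' @export
print.cell_call <- function(x, ...) {
  cat("<cell_call>\n")
  cat(sprintf("  method: %s; %d barcodes called; threshold %g at rank %d\n",
              x$method, length(x$barcodes), x$threshold, x$knee_rank))
  invisible(x)
}

#' @describeIn call_cells `tidy()` returns the diagnostic rank curve as a
#'   tibble (one row per barcode, with chord distance and called flag).
#' @param x A `cell_call` object.
#' @param ... Unused.
#' @method tidy cell_call
#' @export
tidy.cell_call <- function(x, ...) x$curve

#' @describeIn call_cells `glance()` returns a one-row summary (method, knee
#'   rank, threshold, barcodes called).
#' @method glance cell_call
#' @export
glance.cell_call <- function(x, ...) {
  tibble(method = x$method, knee_rank = x$knee_rank,
         threshold = x$threshold, n_called = length(x$barcodes),
         n_barcodes = nrow(x$curve))
}

#' Plot a barcode rank curve with the knee marked
#'
#' @param object A `cell_call` object.
#' @param ... Unused.
#' @return A ggplot: log-log rank curve, called barcodes highlighted, knee
#'   threshold as a dashed line.
#' @method autoplot cell_call
#' @export
autoplot.cell_call <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = filter(curve, .data$called),
                        color = "#2166ac", size = 0.4) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$knee_rank, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "count",
                  title = sprintf("%d cell-associated barcodes (threshold %g)",
                                  length(object$barcodes), object$threshold)) +
    ggplot2::theme_minimal()
}
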