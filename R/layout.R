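#' Fixed read-pair layout for barcoded-bead libraries
#'
#' Describes how a read pair is laid out: R1 carries the cell barcode and the
#' UMI at fixed positions, R2 carries cDNA. The default mirrors a 30-base R1 /
#' 70-base R2 sequencing recipe with a 16-base cell barcode followed by a
#' 12-base UMI on R1 (the last two R1 bases are ignored). Positions are
#' 1-based and inclusive.
#'
#' @param r1_length Length of read 1 in bases.
#' @param r2_length Length of read 2 (cDNA) in bases.
#' @param barcode Integer vector `c(start, end)` of the cell-barcode span in R1.
#' @param umi Integer vector `c(start, end)` of the UMI span in R1.
#'
#' @return An object of class `read_layout`.
#' @examples
#' read_layout()
#' read_layout(barcode = c(1, 12), umi = c(13, 22))
#' @export
read_layout <- function(r1_length = 30L, r2_length = 70L,
                        barcode = c(1L, 16L), umi = c(17L, 28L)) {
  r1_length <- as.integer(r1_length)
  r2_length <- as.integer(r2_length)
  barcode <- as.integer(barcode)
  umi <- as.integer(umi)
  stopifnot(length(barcode) == 2L, length(umi) == 2L)
  if (barcode[1] < 1L || umi[1] < 1L ||
      barcode[2] > r1_length || umi[2] > r1_length) {
    abort("barcode and UMI spans must lie within read 1", class = "layout_error")
  }
  if (barcode[2] < barcode[1] || umi[2] < umi[1]) {
    abort("barcode and UMI spans must be non-empty", class = "layout_error")
  }
  if (max(barcode[1], umi[1]) <= min(barcode[2], umi[2])) {
    abort("barcode and UMI spans must not overlap", class = "layout_error")
  }
  structure(
    list(r1_length = r1_length, r2_length = r2_length,
         barcode = barcode, umi = umi),
    class = "read_layout"
  )
}

barcode_length <- function(layout) layout$barcode[2] - layout$barcode[1] + 1L
umi_length <- function(layout) layout$umi[2] - layout$umi[1] + 1L

#' @export
print.read_layout <- function(x, ...) {
  cat("<read_layout>\n")
  cat(sprintf("  R1: %d bases (barcode %d-%d, UMI %d-%d), R2: %d bases\n",
              x$r1_length, x$barcode[1], x$barcode[2],
              x$umi[1], x$umi[2], x$r2_length))
  invisible(x)
}
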