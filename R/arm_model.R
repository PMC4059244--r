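#' Chromosome-arm coordinate model
#'
#' An `arm_model` fixes the coordinate frame shared by every stage of the
#' pipeline: 0-based half-open bp coordinates along one chromosome arm, with
#' the distal (telomeric) end at coordinate 0 and the proximal (centromeric,
#' FRT-bearing) end at `length_bp`. It carries the arm's genetic length and a
#' cytological band table, the reporting unit for mapped intervals.
#'
#' @param name Arm label, e.g. `"3L"`; also the contig name used in VCF/GFF3.
#' @param length_bp Physical length of the arm in bp.
#' @param genetic_length_cM Genetic length of the arm in centiMorgans; the
#'   expected crossover count per meiosis is `genetic_length_cM / 100`.
#' @param band_table Optional data.frame with columns `band`, `start_bp`,
#'   `end_bp` giving non-overlapping, sorted, half-open intervals that exactly
#'   tile `[0, length_bp)`. When omitted, a synthetic table of equal-width
#'   bands `61A` to `80F` is laid over the arm.
#'
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(name, length_bp, genetic_length_cM = 47,
                      band_table = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            length_bp > 0, genetic_length_cM > 0)
  length_bp <- as.numeric(length_bp)
  if (is.null(band_table)) {
    band_table <- default_band_table(length_bp)
  }
  validate_band_table(band_table, length_bp)
  structure(
    list(name = name, length_bp = length_bp,
         genetic_length_cM = as.numeric(genetic_length_cM),
         orientation = c(distal = "coordinate 0 (telomere)",
                         proximal = "coordinate length_bp (centromere/FRT)"),
         band_table = band_table),
    class = "arm_model")
}

## Bands 61A..80F, equal widths; the last band absorbs any remainder.
default_band_table <- function(length_bp, first_number = 61L,
                               last_number = 80L) {
  labels <- as.vector(t(outer(first_number:last_number, LETTERS[1:6],
                              paste0)))
  n <- length(labels)
  w <- floor(length_bp / n)
  start <- (seq_len(n) - 1L) * w
  end <- c(start[-1L], length_bp)
  data.frame(band = labels, start_bp = start, end_bp = end,
             stringsAsFactors = FALSE)
}

validate_band_table <- function(bt, length_bp) {
  stopifnot(is.data.frame(bt),
            all(c("band", "start_bp", "end_bp") %in% names(bt)))
  if (nrow(bt) == 0L) stop("band table is empty")
  if (anyDuplicated(bt$band)) stop("duplicated band labels in band table")
  o <- order(bt$start_bp)
  if (!identical(o, seq_len(nrow(bt)))) stop("band table is not sorted")
  if (bt$start_bp[1] != 0) stop("band table does not start at 0")
  if (bt$end_bp[nrow(bt)] != length_bp)
    stop("band table does not end at length_bp")
  if (any(bt$end_bp <= bt$start_bp)) stop("empty or inverted band interval")
  if (nrow(bt) > 1L && any(bt$start_bp[-1L] != bt$end_bp[-nrow(bt)]))
    stop("band intervals do not tile the arm")
  invisible(bt)
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf("arm_model '%s': %.0f bp, %.1f cM, %d bands (%s..%s)\n",
              x$name, x$length_bp, x$genetic_length_cM, nrow(x$band_table),
              x$band_table$band[1], x$band_table$band[nrow(x$band_table)]))
  invisible(x)
}

#' Convert a cytological band label to its bp interval
#'
#' @param arm An [arm_model()].
#' @param band A band label present in the arm's band table.
#' @return Numeric vector `c(start_bp, end_bp)`, half-open.
#' @export
band_to_interval <- function(arm, band) {
  i <- match(band, arm$band_table$band)
  if (is.na(i)) stop(sprintf("unknown band label '%s' on arm %s",
                             band, arm$name))
  c(start_bp = arm$band_table$start_bp[i], end_bp = arm$band_table$end_bp[i])
}

#' Convert a bp position to its cytological band label
#'
#' @param arm An [arm_model()].
#' @param bp Position(s) in `[0, length_bp)`.
#' @return Band label(s).
#' @export
bp_to_band <- function(arm, bp) {
  if (any(bp < 0 | bp >= arm$length_bp))
    stop("position outside the arm")
  i <- findInterval(bp, arm$band_table$start_bp)
  arm$band_table$band[i]
}
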