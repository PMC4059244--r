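#' SNP marker panel
#'
#' The set of markers distinguishing the mutagenized chromosome from the
#' SNP-marked mapping chromosome, plus the two anchor markers used for
#' first-stage recombinant classification. By convention the distal anchor
#' has the lower coordinate.
#'
#' @param loci data.frame with columns `snp_id`, `position_bp`, `band`,
#'   `allele_mut`, `allele_map` (parental alleles, which must differ at every
#'   locus). Positions must be strictly increasing.
#' @param distal_anchor,proximal_anchor `snp_id`s of the anchor markers; by
#'   default the first and last locus of the panel.
#' @return An object of class `snp_panel`.
#' @export
snp_panel <- function(loci, distal_anchor = loci$snp_id[1],
                      proximal_anchor = loci$snp_id[nrow(loci)]) {
  stopifnot(is.data.frame(loci),
            all(c("snp_id", "position_bp", "allele_mut", "allele_map")
                %in% names(loci)))
  if (nrow(loci) < 2L) stop("a panel needs at least two loci")
  if (is.unsorted(loci$position_bp, strictly = TRUE))
    stop("panel positions must be strictly increasing")
  if (anyDuplicated(loci$snp_id)) stop("duplicated snp_id in panel")
  if (any(loci$allele_mut == loci$allele_map))
    stop("parental alleles must differ at every panel locus")
  if (!all(c(distal_anchor, proximal_anchor) %in% loci$snp_id))
    stop("anchors must be members of the panel")
  pd <- loci$position_bp[match(distal_anchor, loci$snp_id)]
  pp <- loci$position_bp[match(proximal_anchor, loci$snp_id)]
  if (!(pd < pp))
    stop("distal anchor must lie at a lower coordinate than proximal anchor")
  structure(list(loci = loci,
                 anchors = c(distal = distal_anchor,
                             proximal = proximal_anchor)),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d loci spanning %.0f-%.0f bp; anchors %s / %s\n",
              nrow(x$loci), min(x$loci$position_bp), max(x$loci$position_bp),
              x$anchors[["distal"]], x$anchors[["proximal"]]))
  invisible(x)
}

#' Simulate a dense SNP panel over an arm
#'
#' Markers are laid down with roughly even spacing (one per `spacing_bp`,
#' jittered uniformly within each spacing window), emulating the euchromatic
#' SNP density obtained by sequencing the two parental chromosomes. Parental
#' alleles are arbitrary distinct bases.
#'
#' @param arm An [arm_model()].
#' @param spacing_bp Mean marker spacing in bp (default 1500, i.e. one SNP
#'   per 1.5 kb).
#' @return An `snp_panel` whose anchors are the outermost markers.
#' @export
simulate_snp_panel <- function(arm, spacing_bp = 1500) {
  n <- max(2L, floor(arm$length_bp / spacing_bp))
  w <- arm$length_bp / n
  pos <- floor((seq_len(n) - 1L) * w + stats::runif(n, 0, w))
  pos <- sort(unique(pos))
  mut <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
  map <- vapply(mut, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  loci <- data.frame(
    snp_id = sprintf("SNP_%s", bp_to_band(arm, pos)),
    position_bp = pos, band = bp_to_band(arm, pos),
    allele_mut = mut, allele_map = map, stringsAsFactors = FALSE)
  loci$snp_id <- make.unique(loci$snp_id, sep = ".")
  snp_panel(loci)
}

anchor_index <- function(panel) {
  c(distal = match(panel$anchors[["distal"]], panel$loci$snp_id),
    proximal = match(panel$anchors[["proximal"]], panel$loci$snp_id))
}
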