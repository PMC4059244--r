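#' Gene models on a chromosome arm
#'
#' A `gene_model` is an ordered collection of protein-coding gene structures
#' used to classify lesion effects: exon/intron layout, CDS bounds, strand,
#' and (optionally) the genomic plus-strand sequence of the gene span, which
#' is required for codon-level classification of coding SNVs.
#'
#' @param genes A list of gene entries as built by [make_gene()].
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes) {
  stopifnot(is.list(genes))
  for (g in genes) validate_gene(g)
  starts <- vapply(genes, `[[`, numeric(1), "start")
  o <- order(starts)
  genes <- genes[o]
  structure(list(
    genes = genes,
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, `[[`, numeric(1), "end")),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cds <- sum(vapply(x$genes, gene_cds_length, numeric(1)))
  cat(sprintf("gene_model: %d genes, %.0f bp total CDS\n",
              length(x$genes), cds))
  invisible(x)
}

#' Construct a single gene entry
#'
#' @param gene_id Gene label.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of half-open genomic exon intervals,
#'   sorted and non-overlapping.
#' @param cds_start_bp,cds_end_bp Genomic CDS bounds (half-open); must lie
#'   within the exon union, and the exonic length between them must be a
#'   multiple of 3. Defaults: the whole exon union.
#' @param seq Optional genomic plus-strand sequence of the gene span
#'   `[min(exons), max(exons))` as a single character string.
#' @return A gene entry (plain list) for [gene_model()].
#' @export
make_gene <- function(gene_id, strand, exons,
                      cds_start_bp = min(exons), cds_end_bp = max(exons),
                      seq = NULL) {
  g <- list(gene_id = gene_id, strand = strand,
            exons = matrix(as.numeric(exons), ncol = 2,
                           dimnames = list(NULL, c("start", "end"))),
            cds_start = as.numeric(cds_start_bp),
            cds_end = as.numeric(cds_end_bp),
            start = as.numeric(min(exons)), end = as.numeric(max(exons)),
            seq = seq)
  validate_gene(g)
  g
}

validate_gene <- function(g) {
  ex <- g$exons
  if (nrow(ex) == 0L) stop("gene has no exons: ", g$gene_id)
  if (any(ex[, 2] <= ex[, 1])) stop("empty exon in gene ", g$gene_id)
  if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2]))
    stop("exons overlap or are unsorted in gene ", g$gene_id)
  if (!(g$strand %in% c("+", "-"))) stop("bad strand in gene ", g$gene_id)
  cds <- gene_cds_intervals(g)
  if (nrow(cds) == 0L) stop("CDS outside exon union in gene ", g$gene_id)
  if (sum(cds[, 2] - cds[, 1]) %% 3 != 0)
    stop("CDS length not a multiple of 3 in gene ", g$gene_id)
  if (!is.null(g$seq) && nchar(g$seq) != g$end - g$start)
    stop("sequence length does not match gene span in gene ", g$gene_id)
  invisible(g)
}

## Exonic intervals clipped to the CDS bounds, genomic order.
gene_cds_intervals <- function(g) {
  s <- pmax(g$exons[, 1], g$cds_start)
  e <- pmin(g$exons[, 2], g$cds_end)
  iv(s, e)
}

gene_cds_length <- function(g) iv_width(gene_cds_intervals(g))

## Intron intervals (gaps between consecutive exons), genomic order.
gene_introns <- function(g) {
  if (nrow(g$exons) < 2L) return(iv_empty())
  iv(g$exons[-nrow(g$exons), 2], g$exons[-1L, 1])
}

## 0-based CDS offset (transcription direction) of genomic position p,
## or NA if p is not an exonic CDS position.
genomic_to_cds_offset <- function(g, p) {
  cds <- gene_cds_intervals(g)
  k <- which(cds[, 1] <= p & p < cds[, 2])
  if (length(k) == 0L) return(NA_real_)
  w <- cds[, 2] - cds[, 1]
  if (g$strand == "+") {
    sum(w[seq_len(k - 1L)]) + (p - cds[k, 1])
  } else {
    n <- nrow(cds)
    after <- if (k < n) sum(w[(k + 1L):n]) else 0
    after + (cds[k, 2] - 1 - p)
  }
}

## Genomic position of 0-based CDS offset (transcription direction).
cds_offset_to_genomic <- function(g, off) {
  cds <- gene_cds_intervals(g)
  w <- cds[, 2] - cds[, 1]
  if (g$strand == "-") {
    cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
    w <- rev(w)
  }
  cw <- cumsum(w)
  k <- findInterval(off, c(0, cw[-length(cw)]))
  within <- off - c(0, cw)[k]
  if (g$strand == "+") cds[k, 1] + within else cds[k, 2] - 1 - within
}

## Plus-strand base at genomic position p (requires gene sequence).
gene_base <- function(g, p) {
  if (is.null(g$seq)) return(NA_character_)
  substr(g$seq, p - g$start + 1, p - g$start + 1)
}
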