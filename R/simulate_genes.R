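## Synthetic protein-coding gene models with attached sequence, used by the
## screen simulator and by test fixtures.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                    c("T", "C", "A", "G"), paste0),
                              c("T", "C", "A", "G"), paste0))
STOP_CODONS <- c("TAA", "TAG", "TGA")
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Random open reading frame of a given codon count
#'
#' Draws codons without internal stops, ending in `TAA`. Uses the current
#' RNG state.
#'
#' @param n_codons Total codon count including the stop.
#' @return Character vector of codons.
#' @export
random_cds_codons <- function(n_codons) {
  stopifnot(n_codons >= 2)
  c(sample(NONSTOP_CODONS, n_codons - 1L, replace = TRUE), "TAA")
}

#' Build a synthetic gene with sequence
#'
#' Lays out a gene of `length(codons)` codons at genomic `start`, split into
#' `n_exons` exons separated by introns with canonical GT..AG edges. The CDS
#' spans the whole exon union (no UTRs). `codons` are in translation order;
#' for a minus-strand gene the stored genomic sequence is their reverse
#' complement.
#'
#' @param gene_id Label.
#' @param start Genomic start (bp, 0-based).
#' @param strand `"+"` or `"-"`.
#' @param codons Character vector of codons (translation order); use
#'   [random_cds_codons()] for a random open reading frame.
#' @param n_exons Number of exons (each exon holds a whole number of codons).
#' @param intron_lengths Intron lengths in bp (`n_exons - 1` values,
#'   each >= 4); recycled.
#' @return A gene entry for [gene_model()].
#' @export
make_synthetic_gene <- function(gene_id, start, strand, codons,
                                n_exons = 1L, intron_lengths = 80L) {
  n_codons <- length(codons)
  stopifnot(n_exons >= 1L, n_codons >= n_exons)
  cds <- paste(codons, collapse = "")
  ## split codons across exons (whole codons per exon, >= 1 each)
  cuts <- if (n_exons > 1L)
    sort(sample(seq_len(n_codons - 1L), n_exons - 1L)) else integer(0)
  exon_codons <- diff(c(0L, cuts, n_codons))
  exon_lens <- exon_codons * 3L
  il <- rep_len(as.integer(intron_lengths), max(n_exons - 1L, 0L))
  if (any(il < 4L)) stop("introns must be at least 4 bp (GT..AG)")
  ## sense-direction pieces: exon1, intron1, exon2, ...
  off <- cumsum(c(0L, head(exon_lens, -1L) + il))
  pieces <- character(2L * n_exons - 1L)
  pos <- 1L
  for (i in seq_len(n_exons)) {
    pieces[2L * i - 1L] <- substr(cds, pos, pos + exon_lens[i] - 1L)
    pos <- pos + exon_lens[i]
    if (i < n_exons)
      pieces[2L * i] <- paste0("GT", random_dna(il[i] - 4L), "AG")
  }
  sense <- paste(pieces, collapse = "")
  span <- nchar(sense)
  ex_sense <- cbind(off, off + exon_lens)  # sense-direction exon offsets
  if (strand == "+") {
    seq <- sense
    exons <- ex_sense + start
  } else {
    seq <- revcomp(sense)
    exons <- cbind(span - ex_sense[, 2], span - ex_sense[, 1]) + start
    exons <- exons[rev(seq_len(n_exons)), , drop = FALSE]
  }
  make_gene(gene_id, strand, exons, seq = seq)
}

#' Simulate a gene model for a chromosome arm
#'
#' Genes are placed along the arm with random inter-gene gaps until the total
#' CDS reaches `coding_fraction` of the arm length. The default coding
#' fraction (0.22) is calibrated so that, combined with the EMS substitution
#' spectrum, an arm carrying one lesion per 400 kb yields on the order of ten
#' lesions with protein-coding consequences — the expectation for a
#' mutagenized Drosophila chromosome arm.
#'
#' @param arm An [arm_model()].
#' @param coding_fraction Target fraction of the arm covered by CDS.
#' @param mean_cds_codons Mean gene CDS size in codons.
#' @param max_exons Maximum exons per gene.
#' @param intron_bp Range of intron lengths (bp).
#' @return A [gene_model()] with sequences attached.
#' @export
simulate_gene_model <- function(arm, coding_fraction = 0.22,
                                mean_cds_codons = 700, max_exons = 4L,
                                intron_bp = c(60, 800)) {
  L <- arm$length_bp
  target <- coding_fraction * L
  n <- max(1L, ceiling(target / (mean_cds_codons * 3)))
  codon_counts <- pmax(100L, round(stats::rnorm(n, mean_cds_codons,
                                                mean_cds_codons / 3)))
  n_ex <- sample.int(max_exons, n, replace = TRUE)
  genes <- vector("list", n)
  spans <- numeric(n)
  protos <- vector("list", n)
  for (i in seq_len(n)) {
    il <- round(stats::runif(max(n_ex[i] - 1L, 1L), intron_bp[1], intron_bp[2]))
    protos[[i]] <- list(codons = random_cds_codons(codon_counts[i]),
                        n_ex = n_ex[i], il = il)
    spans[i] <- codon_counts[i] * 3 + if (n_ex[i] > 1L) sum(il) else 0
  }
  free <- L - sum(spans)
  if (free < 0) stop("arm too short for the requested coding fraction")
  gaps <- diff(c(0, sort(stats::runif(n)), 1)) * free
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    genes[[i]] <- make_synthetic_gene(
      sprintf("gene%04d", i), start = floor(pos),
      strand = sample(c("+", "-"), 1L),
      codons = protos[[i]]$codons, n_exons = protos[[i]]$n_ex,
      intron_lengths = protos[[i]]$il)
    pos <- pos + spans[i]
  }
  gene_model(genes)
}
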