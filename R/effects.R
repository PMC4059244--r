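#' Lesion tables
#'
#' Lesions are represented as a data.frame with one row per variant and
#' columns `id`, `position_bp` (0-based), `kind` (`snv`, `deletion`,
#' `insertion`), `ref`, `alt`. For deletions `ref` holds the deleted
#' sequence (or a run of `N`s of the right length) and `alt` is empty; for
#' insertions `alt` holds the inserted sequence or an element label such as
#' `HOBO`.
#'
#' @param id,position_bp,kind,ref,alt Column vectors, recycled to a common
#'   length.
#' @return A `data.frame` of lesions, sorted by position.
#' @export
lesion_table <- function(id, position_bp, kind = "snv", ref = "N", alt = "N") {
  df <- data.frame(id = as.character(id),
                   position_bp = as.numeric(position_bp),
                   kind = as.character(kind), ref = as.character(ref),
                   alt = as.character(alt), stringsAsFactors = FALSE)
  bad <- df$kind == "snv" &
    (nchar(df$ref) != 1L | nchar(df$alt) != 1L | df$ref == df$alt)
  if (any(bad)) stop("invalid snv lesion(s): ", paste(df$id[bad], collapse = ", "))
  if (!all(df$kind %in% c("snv", "deletion", "insertion")))
    stop("lesion kind must be snv, deletion or insertion")
  df[order(df$position_bp), , drop = FALSE]
}

deletion_length <- function(lesions) {
  ifelse(lesions$kind == "deletion", nchar(lesions$ref), 0L)
}

## Effect classes with protein-coding consequences (candidate classes).
CODING_CLASSES <- c("nonsense", "missense", "stop_lost", "splice_acceptor",
                    "splice_donor", "frameshift_deletion", "inframe_deletion",
                    "insertion_disruption")

ALL_EFFECT_CLASSES <- c(CODING_CLASSES, "synonymous", "intronic", "utr",
                        "intergenic")

#' Classify the coding effect of one lesion
#'
#' Deterministic, total classification against a gene model. Rules: codon
#' changes are read through the standard nuclear code (strand-aware); the
#' first 2 bp (GT donor) and last 2 bp (AG acceptor) of every intron are
#' splice sites; a deletion removing coding sequence is a frameshift unless
#' the removed CDS length is a multiple of 3; any insertion falling inside a
#' gene span disrupts it; anything outside all gene spans is intergenic.
#' Codon numbering is 1-based from the annotated CDS start, giving protein
#' changes in the conventional `Q33>stop` style.
#'
#' @param lesion One-row lesion data.frame (see [lesion_table()]).
#' @param genes A [gene_model()].
#' @param on_ref_mismatch What to do when the lesion's stated reference
#'   allele contradicts the gene model's sequence: `"error"` (default) or
#'   `"flag"` (classify anyway and set `ref_mismatch = TRUE`).
#' @return One-row data.frame: lesion columns plus `gene_id`,
#'   `effect_class`, `protein_change`, `ref_mismatch`.
#' @export
classify_effect <- function(lesion, genes,
                            on_ref_mismatch = c("error", "flag")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  stopifnot(nrow(lesion) == 1L)
  p <- lesion$position_bp
  len <- if (lesion$kind == "deletion") nchar(lesion$ref) else 1L
  hit <- which(genes$start < p + len & p < genes$end)
  out <- cbind(lesion,
               data.frame(gene_id = NA_character_,
                          effect_class = "intergenic",
                          protein_change = NA_character_,
                          ref_mismatch = FALSE, stringsAsFactors = FALSE))
  if (length(hit) == 0L) return(out)
  g <- genes$genes[[hit[1L]]]
  out$gene_id <- g$gene_id

  mism <- FALSE
  if (!is.null(g$seq) && lesion$kind == "snv") {
    b <- gene_base(g, p)
    if (!is.na(b) && toupper(b) != toupper(lesion$ref)) {
      if (on_ref_mismatch == "error")
        stop(sprintf("lesion %s: ref allele %s contradicts gene %s sequence (%s) at %d",
                     lesion$id, lesion$ref, g$gene_id, b, p))
      mism <- TRUE
    }
  }
  out$ref_mismatch <- mism

  if (lesion$kind == "insertion") {
    out$effect_class <- "insertion_disruption"
    return(out)
  }

  introns <- gene_introns(g)
  splice_class <- function(lo, hi) {
    ## does [lo, hi) touch a +/-2 bp intron edge? returns class or NULL
    for (j in seq_len(nrow(introns))) {
      a <- introns[j, 1]; b <- introns[j, 2]
      don <- if (g$strand == "+") c(a, a + 2) else c(b - 2, b)
      acc <- if (g$strand == "+") c(b - 2, b) else c(a, a + 2)
      if (lo < don[2] && hi > don[1]) return("splice_donor")
      if (lo < acc[2] && hi > acc[1]) return("splice_acceptor")
    }
    NULL
  }

  if (lesion$kind == "deletion") {
    cds <- gene_cds_intervals(g)
    del_cds <- sum(pmax(0, pmin(cds[, 2], p + len) - pmax(cds[, 1], p)))
    sc <- splice_class(p, p + len)
    if (del_cds > 0) {
      out$effect_class <- if (del_cds %% 3 == 0) "inframe_deletion"
                          else "frameshift_deletion"
    } else if (!is.null(sc)) {
      out$effect_class <- sc
    } else if (iv_overlaps(iv(g$exons[, 1], g$exons[, 2]), p, p + len)) {
      out$effect_class <- "utr"
    } else {
      out$effect_class <- "intronic"
    }
    return(out)
  }

  ## snv
  in_exon <- any(g$exons[, 1] <= p & p < g$exons[, 2])
  if (!in_exon) {
    sc <- splice_class(p, p + 1)
    out$effect_class <- if (is.null(sc)) "intronic" else sc
    return(out)
  }
  off <- genomic_to_cds_offset(g, p)
  if (is.na(off)) {
    out$effect_class <- "utr"
    return(out)
  }
  if (is.null(g$seq))
    stop(sprintf("gene %s carries no sequence; cannot classify coding SNV %s",
                 g$gene_id, lesion$id))
  codon_i <- off %/% 3
  cpos <- codon_i * 3 + 0:2
  gpos <- vapply(cpos, function(o) cds_offset_to_genomic(g, o), numeric(1))
  bases <- vapply(gpos, function(q) gene_base(g, q), character(1))
  if (g$strand == "-") bases <- comp_base(bases)
  codon_ref <- toupper(paste(bases, collapse = ""))
  alt_sense <- if (g$strand == "+") lesion$alt else comp_base(lesion$alt)
  k <- which(gpos == p)
  codon_alt <- codon_ref
  substr(codon_alt, k, k) <- toupper(alt_sense)
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[codon_ref]); aa_alt <- unname(gc[codon_alt])
  disp <- function(aa) if (aa == "*") "stop" else aa
  out$protein_change <- sprintf("%s%d>%s", disp(aa_ref), codon_i + 1,
                                disp(aa_alt))
  out$effect_class <-
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  if (out$effect_class == "synonymous") out$protein_change <- NA_character_
  out
}

#' Classify a whole lesion table
#'
#' @inheritParams classify_effect
#' @param lesions Lesion data.frame.
#' @return Data.frame with one classified row per lesion.
#' @export
classify_effects <- function(lesions, genes,
                             on_ref_mismatch = c("error", "flag")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  if (nrow(lesions) == 0L) {
    return(cbind(lesions,
                 data.frame(gene_id = character(0),
                            effect_class = character(0),
                            protein_change = character(0),
                            ref_mismatch = logical(0))))
  }
  do.call(rbind, lapply(seq_len(nrow(lesions)), function(i)
    classify_effect(lesions[i, , drop = FALSE], genes, on_ref_mismatch)))
}

#' Does an effect call qualify as a coding candidate?
#'
#' Truncating, splice-site, frameshift, in-frame-deletion, missense and
#' insertion lesions count as candidate causative coding mutations;
#' synonymous, intronic, UTR and intergenic lesions do not.
#'
#' @param call A classified effect data.frame (or a character vector of
#'   effect classes).
#' @return Logical vector.
#' @export
is_coding_candidate <- function(call) {
  cls <- if (is.character(call)) call else call$effect_class
  cls %in% CODING_CLASSES
}
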