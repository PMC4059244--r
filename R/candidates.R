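#' Rank coding candidates inside a mapped interval
#'
#' Intersects a whole-genome-sequencing lesion list with the mapped
#' interval and ranks the lesions with protein-coding consequences:
#' truncating changes (nonsense, stop-lost, splice-site, frameshift,
#' transposon/insertion disruption) before missense, before in-frame
#' deletions; lesions whose stated reference allele contradicts the gene
#' model are retained but ranked last; ties break by position, distal
#' first. Lesions outside the interval or without coding consequences are
#' classified but unranked.
#'
#' @param lesions Lesion data.frame (raw, or already classified by
#'   [classify_effects()]).
#' @param interval Numeric `c(start_bp, end_bp)`, half-open, or the
#'   `interval_bp` element of a `mapped_result`.
#' @param genes A [gene_model()].
#' @return Data.frame of classified lesions with `in_interval`, `rank`
#'   (NA for non-candidates) and `rationale`, candidates first.
#' @export
candidates_in_interval <- function(lesions, interval, genes) {
  if (is.null(interval) || interval[2] <= interval[1])
    stop("empty or missing mapped interval")
  ann <- if ("effect_class" %in% names(lesions)) lesions
         else classify_effects(lesions, genes, on_ref_mismatch = "flag")
  ann$in_interval <- ann$position_bp >= interval[1] &
    ann$position_bp < interval[2]
  ann$rank <- NA_integer_
  cand <- which(ann$in_interval & is_coding_candidate(ann))
  if (length(cand) > 0L) {
    truncating <- c("nonsense", "stop_lost", "splice_acceptor",
                    "splice_donor", "frameshift_deletion",
                    "insertion_disruption")
    prio <- ifelse(ann$ref_mismatch[cand], 4L,
            ifelse(ann$effect_class[cand] %in% truncating, 1L,
            ifelse(ann$effect_class[cand] == "missense", 2L, 3L)))
    ord <- cand[order(prio, ann$position_bp[cand])]
    ann$rank[ord] <- seq_along(ord)
  }
  ann$rationale <- ifelse(!ann$in_interval, "outside mapped interval",
    ifelse(is.na(ann$rank), paste0("no coding consequence (",
                                   ann$effect_class, ")"),
      paste0(ann$effect_class,
             ifelse(ann$ref_mismatch, "; reference allele mismatch", ""))))
  ann[order(is.na(ann$rank), ann$rank, ann$position_bp), , drop = FALSE]
}

#' Genes mutated in both of two allele lesion lists
#'
#' Allelism by sequence: two independently induced mutant lines that fail
#' to complement should carry coding lesions in the same gene. Reports
#' every gene with at least one coding-candidate lesion in each list.
#'
#' @param lesions_a,lesions_b Lesion data.frames annotated against the
#'   same gene model (raw tables are classified on the fly).
#' @param genes A [gene_model()].
#' @return Data.frame with `gene_id`, `change_a`, `change_b` (protein
#'   changes or effect classes, comma-collapsed per gene).
#' @export
shared_mutated_genes <- function(lesions_a, lesions_b, genes) {
  qual <- function(lesions) {
    ann <- if ("effect_class" %in% names(lesions)) lesions
           else classify_effects(lesions, genes, on_ref_mismatch = "flag")
    ann[is_coding_candidate(ann) & !is.na(ann$gene_id), , drop = FALSE]
  }
  a <- qual(lesions_a); b <- qual(lesions_b)
  shared <- intersect(unique(a$gene_id), unique(b$gene_id))
  change <- function(ann, g) paste(
    ifelse(is.na(ann$protein_change[ann$gene_id == g]),
           ann$effect_class[ann$gene_id == g],
           ann$protein_change[ann$gene_id == g]), collapse = ",")
  data.frame(
    gene_id = shared,
    change_a = vapply(shared, change, character(1), ann = a),
    change_b = vapply(shared, change, character(1), ann = b),
    row.names = NULL, stringsAsFactors = FALSE)
}
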