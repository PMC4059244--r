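#' Deterministic worked-example fixture (the 11R2 mapping cross)
#'
#' Reconstructs, as a fully deterministic data set, the canonical worked
#' example of the mapping strategy: a 23.04-Mb chromosome arm 3L with
#' equal-width cytological bands 61A-80F, a four-marker panel (anchors at
#' 61A and 75F, internal markers at 66F and 69C), and a cohort of 48 F2
#' lines comprising 29 nonrecombinants, 13 recombinants with distal
#' mutagenized-parent homology (3 of them mutant) and 6 with proximal
#' homology (5 mutant). The breakpoints are arranged so that exclusion
#' mapping localizes the causative lesion between bands 66F and 69C with
#' exactly four recombinants retaining breakpoints inside that interval.
#' The lesion list holds one causative nonsense lesion (Q33>stop in a
#' nudE-like gene in band 67D) among decoy lesions that are either outside
#' the interval or non-coding.
#'
#' @return A list with elements `arm`, `panel`, `genes`, `lesions`
#'   (classified lesion table), `causative_ids`, and `cohort`.
#' @export
make_11R2_fixture <- function() {
  arm <- arm_model("3L", 23040000, genetic_length_cM = 47)
  s <- c(SNP_61A = 96000, SNP_66F = 6816000, SNP_69C = 9696000,
         SNP_75F = 17184000)
  panel <- snp_panel(data.frame(
    snp_id = names(s), position_bp = unname(s),
    band = bp_to_band(arm, unname(s)),
    allele_mut = c("A", "G", "C", "T"), allele_map = c("G", "A", "T", "C"),
    stringsAsFactors = FALSE))

  genes <- with_seed(113, {
    cod_67D <- random_cds_codons(300); cod_67D[33] <- "CAG"
    cod_67D[100] <- "CTG"  # leucine: third-position G>A is synonymous
    cod_62B <- random_cds_codons(200); cod_62B[50] <- "GAG"
    cod_75A <- random_cds_codons(250); cod_75A[40] <- "CAA"
    gene_model(list(
      make_synthetic_gene("gene62B.1", 1400000, "+", cod_62B),
      make_synthetic_gene("nudE_like", 7499904, "+", cod_67D),
      make_synthetic_gene("gene75A.1", 16200000, "-", cod_75A,
                          n_exons = 2L, intron_lengths = 120L)))
  })
  g75 <- genes$genes[[match("gene75A.1", genes$gene_id)]]
  p75 <- cds_offset_to_genomic(g75, 39 * 3)     # first base of codon 40
  lesions <- lesion_table(
    id = c("les_62B_missense", "les_67D_nonsense", "les_67D_synonymous",
           "les_68E_intergenic", "les_75A_nonsense", "les_78C_intergenic"),
    position_bp = c(1400000 + 49 * 3, 7499904 + 32 * 3,
                    7499904 + 99 * 3 + 2, 8900000, p75, 20000000),
    kind = "snv",
    ref = c("G", "C", "G", "G", comp_base("C"), "C"),
    alt = c("A", "T", "A", "A", comp_base("T"), "T"))
  ann <- classify_effects(lesions, genes)

  ## line patterns over (61A, 66F, 69C, 75F); M = mutagenized parent origin
  pat <- list(
    list(v = c("MUT", "MUT", "MAP", "MAP"), ph = "wild_type", bk = 7.0e6, n = 1),
    list(v = c("MUT", "MUT", "MAP", "MAP"), ph = "mutant",    bk = 9.0e6, n = 1),
    list(v = c("MUT", "MUT", "MUT", "MAP"), ph = "mutant",    bk = 1.2e7, n = 2),
    list(v = c("MUT", "MAP", "MAP", "MAP"), ph = "wild_type", bk = 3.0e6, n = 9),
    list(v = c("MAP", "MAP", "MUT", "MUT"), ph = "mutant",    bk = 7.2e6, n = 1),
    list(v = c("MAP", "MUT", "MUT", "MUT"), ph = "mutant",    bk = 3.0e6, n = 4),
    list(v = c("MAP", "MAP", "MUT", "MUT"), ph = "wild_type", bk = 9.2e6, n = 1),
    list(v = c("MUT", "MUT", "MUT", "MUT"), ph = "mutant",    bk = NULL,  n = 14),
    list(v = c("MAP", "MAP", "MAP", "MAP"), ph = "wild_type", bk = NULL,  n = 15))
  rows <- do.call(rbind, lapply(pat, function(p)
    matrix(rep(p$v, p$n), ncol = 4, byrow = TRUE)))
  phen <- unlist(lapply(pat, function(p) rep(p$ph, p$n)))
  bks <- unlist(lapply(pat, function(p)
    rep(list(if (is.null(p$bk)) numeric(0) else p$bk), p$n)),
    recursive = FALSE)
  ids <- sprintf("F2_%02d", seq_len(nrow(rows)))
  dimnames(rows) <- list(ids, panel$loci$snp_id)
  cohort <- structure(list(
    lines = data.frame(line_id = ids, phenotype = phen,
                       stringsAsFactors = FALSE),
    calls = rows,
    truth = list(breakpoints = bks,
                 start_parent = ifelse(rows[, 1] == "MUT", "MUT", "MAP")),
    seed = NA_integer_),
    class = "f2_cohort")

  list(arm = arm, panel = panel, genes = genes, lesions = ann,
       causative_ids = "les_67D_nonsense", cohort = cohort)
}
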