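# Small deterministic fixtures built in code.

toy_arm <- function(length_bp = 4e6, cM = 10) {
  arm_model("toyL", length_bp, genetic_length_cM = cM)
}

# Panel with markers at the given positions; anchors = outermost.
toy_panel <- function(positions, arm = toy_arm()) {
  n <- length(positions)
  snp_panel(data.frame(
    snp_id = sprintf("S%02d", seq_len(n)), position_bp = positions,
    band = bp_to_band(arm, positions),
    allele_mut = rep("A", n), allele_map = rep("G", n),
    stringsAsFactors = FALSE))
}

# Cohort from an explicit call matrix and phenotypes (no hidden truth).
toy_cohort <- function(calls, phenotypes, snp_ids) {
  ids <- sprintf("L%02d", seq_len(nrow(calls)))
  dimnames(calls) <- list(ids, snp_ids)
  structure(list(
    lines = data.frame(line_id = ids, phenotype = phenotypes,
                       stringsAsFactors = FALSE),
    calls = calls, truth = NULL, seed = NA_integer_),
    class = "f2_cohort")
}

# One-gene model (plus strand, single exon) whose codons are known.
toy_gene_model <- function(codons, start = 1000, strand = "+",
                           n_exons = 1L, intron_lengths = 50L) {
  gene_model(list(make_synthetic_gene("toyg", start, strand, codons,
                                      n_exons = n_exons,
                                      intron_lengths = intron_lengths)))
}

snv <- function(id, pos, ref, alt) {
  lesion_table(id = id, position_bp = pos, kind = "snv", ref = ref, alt = alt)
}

# Sparse marker panel (1 per 50 kb) for simulation-heavy tests where the
# full 1/1.5 kb density is unnecessary; built once per test run.
sparse_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      so <- study_objects()
      set.seed(9)
      cache <<- simulate_snp_panel(so$arm, spacing_bp = 50000)
    }
    cache
  }
})

# Standard study-condition objects shared by simulation-heavy tests;
# built once per test run.
study_objects <- local({
  cache <- NULL
  function(spacing_bp = 20000) {
    if (is.null(cache)) {
      set.seed(20110607)
      arm <- arm_model("3L", 23e6, genetic_length_cM = 47)
      cache <<- list(arm = arm,
                     genes = simulate_gene_model(arm),
                     panel_dense = simulate_snp_panel(arm, spacing_bp = 1500))
    }
    cache
  }
})
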