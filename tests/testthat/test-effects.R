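# Effect classification oracles: a single-exon gene with hand-chosen codons
# so every expected amino-acid change is known by construction.

known_codons <- function() {
  # ATG M1, CAG Q2, TGG W3, CTG L4, GAA E5, then filler, TAA stop
  c("ATG", "CAG", "TGG", "CTG", "GAA", rep("GCC", 14), "TAA")
}

test_that("codon-level SNV classes match hand-computed translations", {
  g <- toy_gene_model(known_codons(), start = 1000)
  # CAG -> TAG at codon 2 (first base): nonsense
  e <- classify_effect(snv("n1", 1003, "C", "T"), g)
  expect_identical(e$effect_class, "nonsense")
  expect_identical(e$protein_change, "Q2>stop")
  # CTG -> CTA at codon 4 (third base): synonymous, no protein change
  e <- classify_effect(snv("s1", 1011, "G", "A"), g)
  expect_identical(e$effect_class, "synonymous")
  expect_true(is.na(e$protein_change))
  # GAA -> AAA at codon 5: missense E5>K
  e <- classify_effect(snv("m1", 1012, "G", "A"), g)
  expect_identical(e$effect_class, "missense")
  expect_identical(e$protein_change, "E5>K")
  # TAA -> CAA at the stop codon: stop lost
  p_stop <- 1000 + (length(known_codons()) - 1) * 3
  e <- classify_effect(snv("sl", p_stop, "T", "C"), g)
  expect_identical(e$effect_class, "stop_lost")
  expect_identical(e$protein_change, sprintf("stop%d>Q", length(known_codons())))
})

test_that("splice-site and intron classification uses the 2 bp intron edges", {
  set.seed(11)
  g <- toy_gene_model(random_cds_codons(60), start = 500, n_exons = 3L,
                      intron_lengths = c(100L, 60L))
  gene <- g$genes[[1]]
  a <- gene$exons[1, 2]; b <- gene$exons[2, 1]  # first intron [a, b)
  # donor GT -> AT (first intron base)
  e <- classify_effect(snv("d", a, "G", "A"), g)
  expect_identical(e$effect_class, "splice_donor")
  # acceptor AG -> GG (penultimate intron base)
  e <- classify_effect(snv("a", b - 2, "A", "G"), g)
  expect_identical(e$effect_class, "splice_acceptor")
  # intron interior
  mid <- floor((a + b) / 2)
  ref <- substr(gene$seq, mid - gene$start + 1, mid - gene$start + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  e <- classify_effect(snv("i", mid, ref, alt), g)
  expect_identical(e$effect_class, "intronic")
  expect_true(is.na(e$protein_change))
})

test_that("deletion length mod 3 separates frameshift from in-frame", {
  g <- toy_gene_model(known_codons(), start = 1000)
  del <- function(pos, len) lesion_table("d", pos, "deletion",
                                         strrep("N", len), "")
  expect_identical(classify_effect(del(1006, 10), g)$effect_class,
                   "frameshift_deletion")
  expect_identical(classify_effect(del(1006, 9), g)$effect_class,
                   "inframe_deletion")
  # deletion confined to an intron is intronic
  set.seed(12)
  g2 <- toy_gene_model(random_cds_codons(60), start = 500, n_exons = 2L,
                       intron_lengths = 100L)
  gene <- g2$genes[[1]]
  a <- gene$exons[1, 2]
  expect_identical(classify_effect(del(a + 10, 5), g2)$effect_class,
                   "intronic")
})

test_that("insertions disrupt genes; everything else is intergenic", {
  g <- toy_gene_model(known_codons(), start = 1000)
  ins <- function(pos, alt) lesion_table("i", pos, "insertion", "", alt)
  expect_identical(classify_effect(ins(1010, "HOBO"), g)$effect_class,
                   "insertion_disruption")
  expect_identical(classify_effect(ins(5000, "HOBO"), g)$effect_class,
                   "intergenic")
  e <- classify_effect(snv("x", 900, "A", "T"), g)
  expect_identical(e$effect_class, "intergenic")
  expect_true(is.na(e$gene_id))
})

test_that("exonic positions outside the CDS are UTR", {
  seq <- paste0("ACACAC", "ATGGAAGCCGCCGCCTAA", "GTGTGT")
  g <- gene_model(list(make_gene("u", "+", rbind(c(0, 30)),
                                 cds_start_bp = 6, cds_end_bp = 24,
                                 seq = seq)))
  expect_identical(classify_effect(snv("u1", 2, "A", "G"), g)$effect_class,
                   "utr")
  expect_identical(classify_effect(snv("u2", 6, "A", "G"), g)$effect_class,
                   "missense")
})

test_that("minus-strand classification equals the reverse-complement construction", {
  codons <- known_codons()
  n <- length(codons)
  gp <- toy_gene_model(codons, start = 1000, strand = "+")
  gm <- toy_gene_model(codons, start = 1000, strand = "-")
  # codon 5 first base E -> K; sense change G -> A
  off <- 4 * 3
  p_plus <- 1000 + off
  p_minus <- 1000 + 3 * n - 1 - off   # single exon, reverse-complemented
  e_plus <- classify_effect(snv("p", p_plus, "G", "A"), gp)
  e_minus <- classify_effect(snv("m", p_minus, "C", "T"), gm)
  expect_identical(e_minus$effect_class, e_plus$effect_class)
  expect_identical(e_minus$protein_change, e_plus$protein_change)
})

test_that("reference mismatches error by default and can be flagged", {
  g <- toy_gene_model(known_codons(), start = 1000)
  bad <- snv("b", 1003, "G", "T")  # true base is C
  expect_error(classify_effect(bad, g), "contradicts")
  e <- classify_effect(bad, g, on_ref_mismatch = "flag")
  expect_true(e$ref_mismatch)
  expect_identical(e$effect_class, "nonsense")  # still classified
})

test_that("classification is total and deterministic over the arm", {
  set.seed(33)
  g <- toy_gene_model(random_cds_codons(80), start = 2000, n_exons = 2L,
                      intron_lengths = 120L)
  classes <- c("nonsense", "missense", "stop_lost", "splice_acceptor",
               "splice_donor", "frameshift_deletion", "inframe_deletion",
               "insertion_disruption", "synonymous", "intronic", "utr",
               "intergenic")
  gene <- g$genes[[1]]
  for (p in seq(1900, gene$end + 100, by = 7)) {
    ref <- if (p >= gene$start && p < gene$end)
      substr(gene$seq, p - gene$start + 1, p - gene$start + 1) else "A"
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    e1 <- classify_effect(snv("x", p, ref, alt), g)
    e2 <- classify_effect(snv("x", p, ref, alt), g)
    expect_identical(e1$effect_class, e2$effect_class)
    expect_true(e1$effect_class %in% classes)
  }
})

test_that("candidate classes are the protein-affecting ones", {
  expect_true(all(is_coding_candidate(c("nonsense", "missense",
                                        "splice_acceptor", "splice_donor",
                                        "frameshift_deletion",
                                        "inframe_deletion", "stop_lost",
                                        "insertion_disruption"))))
  expect_false(any(is_coding_candidate(c("synonymous", "intronic", "utr",
                                         "intergenic"))))
})
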