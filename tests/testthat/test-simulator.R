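# Simulator: lesion statistics, meiosis model, cohort construction,
# worked-example fixture. Monte-Carlo checks run under fixed seeds and are
# compared against closed forms computed independently.

test_that("lesion count is Poisson with mean length x rate", {
  so <- study_objects()
  set.seed(101)
  cfg <- sim_config()
  counts <- replicate(300, nrow(simulate_lesions(so$arm, so$genes,
                                                 cfg)$lesions))
  mu <- so$arm$length_bp * cfg$lesion_rate_per_bp  # 57.5
  expect_equal(mu, 57.5)
  # sample mean within 4 standard errors of the Poisson mean
  se <- sqrt(mu / length(counts))
  expect_lt(abs(mean(counts) - mu), 4 * se)
  # and the variance is Poisson-like, not degenerate
  expect_gt(stats::var(counts), mu / 2)
  expect_lt(stats::var(counts), mu * 2)
})

test_that("the default gene model yields about ten coding-candidate lesions per arm", {
  so <- study_objects()
  set.seed(102)
  cfg <- sim_config()
  nq <- replicate(200, {
    mut <- simulate_lesions(so$arm, so$genes, cfg)
    sum(is_coding_candidate(mut$lesions))
  })
  expect_gt(mean(nq), 8)
  expect_lt(mean(nq), 12)
})

test_that("a zero lesion rate with an injected causative lesion gives exactly that lesion", {
  arm <- toy_arm(1e6)
  set.seed(103)
  # codon 2 is CAG so C>T at its first base is a nonsense by construction
  genes <- toy_gene_model(c("ATG", "CAG", rep("GCC", 10), "TAA"),
                          start = 1000)
  les <- lesion_table("inj1", 1003, "snv", "C", "T")
  expect_true(is_coding_candidate(classify_effect(les, genes)))
  cfg <- sim_config(lesion_rate_per_bp = 0)
  mut <- simulate_lesions(arm, genes, cfg, inject = les)
  expect_equal(nrow(mut$lesions), 1L)
  expect_identical(mut$causative_ids, "inj1")
})

test_that("simulate_lesions fails clearly when no lesion can qualify", {
  arm <- toy_arm(1e6)
  set.seed(104)
  genes <- gene_model(list(make_synthetic_gene("g", 100, "+",
                                               random_cds_codons(10))))
  cfg <- sim_config(lesion_rate_per_bp = 0)
  expect_error(simulate_lesions(arm, genes, cfg, max_resample = 3),
               "coding consequence")
})

test_that("EMS spectrum is G/C to A/T biased", {
  so <- study_objects()
  set.seed(105)
  cfg <- sim_config()
  les <- do.call(rbind, replicate(50, simulate_lesions(
    so$arm, so$genes, cfg)$lesions[, c("ref", "alt")], simplify = FALSE))
  gc <- les$ref %in% c("G", "C")
  trans <- (les$ref == "G" & les$alt == "A") |
    (les$ref == "C" & les$alt == "T")
  expect_gt(mean(trans[gc]), 0.85)
})

test_that("meiosis crossover counts and positions follow the Poisson model", {
  arm <- toy_arm(1e6, cM = 47)
  expect_identical(simulate_meiosis(arm, 0), numeric(0))
  set.seed(106)
  n <- 10000
  ge1 <- mean(replicate(n, length(simulate_meiosis(arm, 0.47)) >= 1))
  expected <- 1 - exp(-0.47)  # 0.375
  expect_lt(abs(ge1 - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("simulated recombination fractions follow the Haldane map function", {
  arm <- toy_arm(10e6, cM = 40)
  set.seed(107)
  n <- 8000
  # loci pairs at increasing separation; d in Morgans
  pairs <- list(c(1e6, 3e6), c(1e6, 6e6), c(0.5e6, 9.5e6))
  for (pr in pairs) {
    d <- 0.40 * (pr[2] - pr[1]) / arm$length_bp
    rec <- replicate(n, {
      bk <- simulate_meiosis(arm, 0.40)
      sum(bk > pr[1] & bk <= pr[2]) %% 2 == 1
    })
    haldane <- (1 - exp(-2 * d)) / 2
    expect_lt(abs(mean(rec) - haldane),
              4 * sqrt(haldane * (1 - haldane) / n) + 0.002)
  }
})

test_that("cohorts without crossovers are pure parental products with truthful phenotypes", {
  so <- study_objects()
  set.seed(108)
  cfg <- sim_config(crossover_mean = 0, n_f2_lines = 30)
  mut <- simulate_lesions(so$arm, so$genes, cfg)
  co <- make_f2_cohort(mut, so$panel_dense, so$arm, so$genes, cfg)
  for (i in seq_len(nrow(co$calls))) {
    v <- unique(co$calls[i, ])
    expect_length(v, 1L)
    expect_identical(co$lines$phenotype[i],
                     if (v == "MUT") "mutant" else "wild_type")
  }
})

test_that("origin vectors are consistent with hidden breakpoints and phenotype with truth", {
  so <- study_objects()
  set.seed(109)
  cfg <- sim_config(n_f2_lines = 200)
  mut <- simulate_lesions(so$arm, so$genes, cfg)
  caus <- mut$lesions$position_bp[mut$lesions$id %in% mut$causative_ids]
  co <- make_f2_cohort(mut, so$panel_dense, so$arm, so$genes, cfg)
  pos <- so$panel_dense$loci$position_bp
  for (i in seq_len(nrow(co$calls))) {
    bk <- co$truth$breakpoints[[i]]
    sp <- co$truth$start_parent[i]
    other <- if (sp == "MUT") "MAP" else "MUT"
    expected <- ifelse(findInterval(pos, bk) %% 2 == 0, sp, other)
    expect_identical(unname(co$calls[i, ]), expected)
    carries <- ifelse(findInterval(caus, bk) %% 2 == 0, sp, other) == "MUT"
    expect_identical(co$lines$phenotype[i],
                     if (any(carries)) "mutant" else "wild_type")
  }
})

test_that("identical config and seed reproduce the cohort exactly", {
  so <- study_objects()
  cfg <- sim_config(seed = 42)
  run <- function() {
    set.seed(cfg$seed)
    mut <- simulate_lesions(so$arm, so$genes, cfg)
    list(mut = mut, co = make_f2_cohort(mut, so$panel_dense, so$arm,
                                        so$genes, cfg))
  }
  a <- run(); b <- run()
  expect_identical(a$mut, b$mut)
  expect_identical(a$co, b$co)
})

test_that("genotype failure and miscall rates corrupt calls at the configured rates", {
  so <- study_objects()
  set.seed(110)
  cfg <- sim_config(n_f2_lines = 40, genotype_fail_rate = 0.1,
                    genotype_miscall_rate = 0.05)
  mut <- simulate_lesions(so$arm, so$genes, cfg)
  co <- make_f2_cohort(mut, so$panel_dense, so$arm, so$genes, cfg)
  fail_rate <- mean(co$calls == "FAIL")
  expect_lt(abs(fail_rate - 0.1), 0.01)
})

test_that("the worked-example fixture reproduces the published cross", {
  fx <- make_11R2_fixture()
  expect_equal(nrow(fx$cohort$calls), 48L)
  cl <- classify_recombinants(fx$cohort, fx$panel)
  expect_equal(sum(cl == "group1_distal_mut"), 13L)
  expect_equal(sum(cl == "group2_proximal_mut"), 6L)
  expect_equal(sum(cl == "group3_nonrecombinant"), 29L)
  mut <- fx$cohort$lines$phenotype == "mutant"
  expect_equal(sum(mut & cl == "group1_distal_mut"), 3L)
  expect_equal(sum(mut & cl == "group2_proximal_mut"), 5L)
  # deterministic constructor
  expect_identical(fx$cohort, make_11R2_fixture()$cohort)
  expect_identical(fx$lesions, make_11R2_fixture()$lesions)
  # causative lesion is a nonsense Q33>stop in band 67D
  caus <- fx$lesions[fx$lesions$id == fx$causative_ids, ]
  expect_identical(caus$effect_class, "nonsense")
  expect_identical(caus$protein_change, "Q33>stop")
})
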