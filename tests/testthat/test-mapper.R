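# Exclusion mapping: segment inference oracles, anchor classification,
# direction inference, conflict quarantine, and agreement with an
# independent brute-force consistency check.

test_that("certain segments close at outer markers and extend to arm ends", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 1e6, 2e6, 3e6, 3.9e6), arm)
  s <- infer_segments(c("MUT", "MUT", "MAP", "MAP", "MAP"), panel, arm)
  expect_equal(s$runs$origin, c("MUT", "MAP"))
  expect_equal(s$runs$start_bp, c(0, 2e6))
  expect_equal(s$runs$end_bp, c(1e6 + 1, 4e6))
  expect_equal(s$gaps$start_bp, 1e6 + 1)
  expect_equal(s$gaps$end_bp, 2e6)
  expect_equal(unname(s$certainly_mut), rbind(c(0, 1e6 + 1)))
  expect_equal(unname(s$certainly_map), rbind(c(2e6, 4e6)))
})

test_that("failed calls widen the uncertainty gap to informative neighbours", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 1e6, 2e6, 3e6, 3.9e6), arm)
  s <- infer_segments(c("MUT", "FAIL", "FAIL", "MAP", "MAP"), panel, arm)
  expect_equal(s$gaps$start_bp, 1e5 + 1)
  expect_equal(s$gaps$end_bp, 3e6)
  expect_equal(unname(s$certainly_mut), rbind(c(0, 1e5 + 1)))
  # a line with no usable calls is uninformative
  s0 <- infer_segments(rep("FAIL", 5), panel, arm)
  expect_false(s0$informative)
  expect_equal(nrow(s0$runs), 0L)
})

test_that("anchor classification assigns the four line classes", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 2e6, 3.9e6), arm)
  calls <- rbind(c("MUT", "MUT", "MAP"),
                 c("MAP", "FAIL", "MUT"),
                 c("MUT", "MAP", "MUT"),
                 c("FAIL", "MUT", "MUT"))
  co <- toy_cohort(calls, rep("mutant", 4), panel$loci$snp_id)
  cl <- classify_recombinants(co, panel)
  expect_identical(unname(cl),
                   c("group1_distal_mut", "group2_proximal_mut",
                     "group3_nonrecombinant", "uninformative_fail"))
  expect_identical(names(cl), co$lines$line_id)
})

test_that("map direction follows the larger group mutant fraction and ties are undetermined", {
  cl <- c("group1_distal_mut", "group1_distal_mut",
          "group2_proximal_mut", "group2_proximal_mut")
  d <- stage1_direction(cl, c("wild_type", "wild_type", "mutant", "weak"))
  expect_identical(d$direction, "proximal")
  expect_equal(d$group2, c(mutant = 2L, total = 2L))
  d <- stage1_direction(cl, c("mutant", "mutant", "wild_type", "wild_type"))
  expect_identical(d$direction, "distal")
  d <- stage1_direction(cl, c("mutant", "wild_type", "mutant", "wild_type"))
  expect_identical(d$direction, "undetermined")
  # one group empty: no fraction comparison possible
  d <- stage1_direction(rep("group1_distal_mut", 3),
                        c("mutant", "mutant", "wild_type"))
  expect_identical(d$direction, "undetermined")
})

test_that("hand-built exclusions shrink the interval exactly as computed by hand", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 1e6, 3e6, 3.9e6), arm)
  calls <- rbind(c("MUT", "MUT", "MAP", "MAP"),   # mutant: excludes [3e6, 4e6)
                 c("MUT", "MAP", "MAP", "MAP"))   # wild:   excludes [0, 1e5+1)
  co <- toy_cohort(calls, c("mutant", "wild_type"), panel$loci$snp_id)
  m <- exclusion_map(co, panel, arm)
  expect_identical(m$status, "consistent")
  expect_equal(unname(m$interval_bp), c(1e5 + 1, 3e6))
  expect_length(m$exclusions, 2L)
  expect_match(m$exclusions$L01$rule, "mapping-origin")
  expect_match(m$exclusions$L02$rule, "mutagenized-origin")
  # both lines still have their uncertainty gap inside the interval
  expect_setequal(m$remaining_informative, c("L01", "L02"))
})

test_that("a line whose exclusion would empty the interval is quarantined", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 1e6, 3e6, 3.9e6), arm)
  calls <- rbind(c("MUT", "MUT", "MAP", "MAP"),
                 c("MUT", "MAP", "MAP", "MAP"),
                 c("MUT", "MUT", "MUT", "MAP"))  # wild type yet MUT to 3e6+1
  co <- toy_cohort(calls, c("mutant", "wild_type", "wild_type"),
                   panel$loci$snp_id)
  m <- exclusion_map(co, panel, arm)
  expect_identical(m$conflicts, "L03")
  # the quarantined line contributed nothing: interval as without it
  expect_equal(unname(m$interval_bp), c(1e5 + 1, 3e6))
  # within the default 5% tolerance of 3 used lines this stays consistent
  expect_identical(m$status, "consistent")
  # with zero tolerance the same data escalate to conflicted
  m0 <- exclusion_map(co, panel, arm, epsilon = 0)
  expect_identical(m0$status, "conflicted")
  expect_null(m0$interval_bp)
  expect_null(m0$interval_bands)
})

test_that("nonrecombinant lines are ignored by default but usable on request", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 1e6, 3e6, 3.9e6), arm)
  # group 3 wild-type line whose internal genotypes would exclude [0, 1e6+1)
  calls <- rbind(c("MUT", "MUT", "MAP", "MAP"),
                 c("MUT", "MUT", "MAP", "MUT"))
  co <- toy_cohort(calls, c("mutant", "wild_type"), panel$loci$snp_id)
  m_def <- exclusion_map(co, panel, arm)
  expect_equal(unname(m_def$interval_bp), c(0, 3e6))
  expect_equal(m_def$n_informative_recombinants, 1L)
  m_all <- exclusion_map(co, panel, arm, recombinants_only = FALSE)
  expect_equal(unname(m_all$interval_bp), c(1e6 + 1, 3e6))
})

test_that("an anchors-only panel recovers the single-marker exclusion geometry", {
  arm <- toy_arm(4e6)
  panel <- toy_panel(c(1e5, 3.9e6), arm)
  co <- toy_cohort(rbind(c("MUT", "MAP")), "mutant", panel$loci$snp_id)
  m <- exclusion_map(co, panel, arm)
  expect_equal(unname(m$interval_bp), c(0, 3.9e6))
  expect_identical(m$remaining_informative, "L01")
})

test_that("the worked-example cohort maps to 66F-69C with four remaining informative lines", {
  fx <- make_11R2_fixture()
  m <- exclusion_map(fx$cohort, fx$panel, fx$arm)
  expect_identical(m$status, "consistent")
  expect_identical(unname(m$interval_bands), c("66F", "69C"))
  expect_identical(m$direction, "proximal")
  expect_equal(m$group_counts$group1, c(mutant = 3L, total = 13L))
  expect_equal(m$group_counts$group2, c(mutant = 5L, total = 6L))
  expect_equal(m$group_counts$group3[["total"]], 29L)
  expect_length(m$remaining_informative, 4L)
  # the true lesion lies inside the mapped interval
  caus <- fx$lesions$position_bp[fx$lesions$id == fx$causative_ids]
  expect_true(caus >= m$interval_bp[["start_bp"]] &&
                caus < m$interval_bp[["end_bp"]])
  # the printed summary reports the same bands
  txt <- paste(format_mapping_summary(m), collapse = "\n")
  expect_match(txt, "66F")
  expect_match(txt, "69C")
})

test_that("exclusion mapping agrees with a brute-force consistency oracle", {
  so <- study_objects()
  set.seed(301)
  panel <- simulate_snp_panel(so$arm, spacing_bp = 50000)
  step <- 10000
  for (rep in 1:15) {
    cfg <- sim_config(n_f2_lines = 48)
    mut <- simulate_lesions(so$arm, so$genes, cfg)
    co <- make_f2_cohort(mut, panel, so$arm, so$genes, cfg)
    m <- exclusion_map(co, panel, so$arm)
    keep <- brute_force_consistency(co, panel, so$arm, grid_step = step)
    expect_identical(m$status, "consistent")
    expect_gt(length(keep), 0)
    # hulls match to grid resolution
    expect_lt(abs(min(keep) - m$interval_bp[["start_bp"]]), step + 1)
    expect_lt(abs(max(keep) + step - m$interval_bp[["end_bp"]]), step + 1)
    # every retained grid point sits inside a remaining region
    expect_true(all(vapply(keep, function(p)
      iv_contains_point(m$remaining_regions, p), logical(1))))
  }
})

test_that("using more phenotyped lines never widens the mapped interval", {
  so <- study_objects()
  set.seed(302)
  panel <- simulate_snp_panel(so$arm, spacing_bp = 50000)
  for (rep in 1:10) {
    cfg <- sim_config(n_f2_lines = 60)
    mut <- simulate_lesions(so$arm, so$genes, cfg)
    co <- make_f2_cohort(mut, panel, so$arm, so$genes, cfg)
    sub <- co
    idx <- 1:30
    sub$lines <- co$lines[idx, , drop = FALSE]
    sub$calls <- co$calls[idx, , drop = FALSE]
    m_sub <- exclusion_map(sub, panel, so$arm)
    m_all <- exclusion_map(co, panel, so$arm)
    expect_lte(m_sub$interval_bp[["start_bp"]], m_all$interval_bp[["start_bp"]])
    expect_gte(m_sub$interval_bp[["end_bp"]], m_all$interval_bp[["end_bp"]])
  }
})
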