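#' Classify recombinants from the two anchor SNPs
#'
#' First-stage classification of each F2 line by the parent of origin of
#' the distal and proximal anchor markers: group 1 (distal mutagenized /
#' proximal mapping), group 2 (the reverse), group 3 (nonrecombinant), or
#' uninformative when either anchor call failed.
#'
#' @param cohort An `f2_cohort`.
#' @param panel The matching [snp_panel()].
#' @return Character vector (one per line) of
#'   `group1_distal_mut`, `group2_proximal_mut`, `group3_nonrecombinant`,
#'   `uninformative_fail`, named by line id.
#' @export
classify_recombinants <- function(cohort, panel) {
  ai <- anchor_index(panel)
  d <- cohort$calls[, ai[["distal"]]]
  p <- cohort$calls[, ai[["proximal"]]]
  out <- ifelse(d == "FAIL" | p == "FAIL", "uninformative_fail",
         ifelse(d == "MUT" & p == "MAP", "group1_distal_mut",
         ifelse(d == "MAP" & p == "MUT", "group2_proximal_mut",
                "group3_nonrecombinant")))
  stats::setNames(out, cohort$lines$line_id)
}

#' Approximate map direction from group mutant fractions
#'
#' The ratio of mutant to wild-type recombinants in the two anchor-defined
#' groups places the lesion nearer one anchor: a higher mutant fraction in
#' group 2 (proximal mutagenized homology) pulls the lesion toward the
#' proximal anchor, and vice versa. Weak phenotypes count as mutant.
#'
#' @param classes Output of [classify_recombinants()].
#' @param phenotypes Character vector of phenotypes, same order.
#' @return List with `direction` (`"proximal"`, `"distal"` or
#'   `"undetermined"`) and per-group `(mutant, total)` counts.
#' @export
stage1_direction <- function(classes, phenotypes) {
  mut <- phenotypes %in% c("mutant", "weak")
  g1 <- classes == "group1_distal_mut"
  g2 <- classes == "group2_proximal_mut"
  f <- function(sel) c(mutant = sum(mut & sel), total = sum(sel))
  c1 <- f(g1); c2 <- f(g2)
  direction <- "undetermined"
  if (c1[["total"]] > 0 && c2[["total"]] > 0) {
    fr1 <- c1[["mutant"]] / c1[["total"]]
    fr2 <- c2[["mutant"]] / c2[["total"]]
    if (fr2 > fr1) direction <- "proximal"
    else if (fr1 > fr2) direction <- "distal"
  }
  list(direction = direction, group1 = c1, group2 = c2)
}

#' Infer certain-origin segments and uncertainty gaps for one line
#'
#' Maximal runs of identical non-FAIL parent-of-origin calls become certain
#' segments, closed at their outermost informative markers; terminal runs
#' extend to the arm end on their side (no marker beyond them can
#' contradict). Between runs of different origin lies an uncertainty gap
#' bounded by the flanking informative markers; failed calls widen gaps to
#' the nearest informative neighbours.
#'
#' @param calls Character vector of MUT/MAP/FAIL calls, panel order.
#' @param panel The [snp_panel()].
#' @param arm The [arm_model()].
#' @return List: `runs` (data.frame origin/start_bp/end_bp, half-open),
#'   `gaps` (data.frame start_bp/end_bp, half-open), `certainly_mut` and
#'   `certainly_map` (interval matrices), `informative` (logical).
#' @export
infer_segments <- function(calls, panel, arm) {
  pos <- panel$loci$position_bp
  keep <- calls != "FAIL"
  if (!any(keep))
    return(list(runs = data.frame(origin = character(0), start_bp = numeric(0),
                                  end_bp = numeric(0)),
                gaps = data.frame(start_bp = numeric(0), end_bp = numeric(0)),
                certainly_mut = iv_empty(), certainly_map = iv_empty(),
                informative = FALSE))
  v <- calls[keep]; q <- pos[keep]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  run_s <- q[starts]; run_e <- q[ends] + 1  # closed at outer SNPs
  run_s[1L] <- 0; run_e[length(run_e)] <- arm$length_bp
  runs <- data.frame(origin = r$values, start_bp = run_s, end_bp = run_e,
                     stringsAsFactors = FALSE)
  gaps <- if (length(run_s) > 1L)
    data.frame(start_bp = q[ends[-length(ends)]] + 1,
               end_bp = q[starts[-1L]])
  else data.frame(start_bp = numeric(0), end_bp = numeric(0))
  list(runs = runs, gaps = gaps,
       certainly_mut = iv(runs$start_bp[runs$origin == "MUT"],
                          runs$end_bp[runs$origin == "MUT"]),
       certainly_map = iv(runs$start_bp[runs$origin == "MAP"],
                          runs$end_bp[runs$origin == "MAP"]),
       informative = TRUE)
}

#' Map the causative interval by exclusion
#'
#' For every phenotyped line, the regions whose parental origin contradicts
#' the phenotype are excluded: a wild-type line excludes its
#' certainly-mutagenized regions (it would otherwise carry the lesion) and
#' a mutant line its certainly-mapping regions. Weak phenotypes count as
#' mutant in single-locus mode. Exclusions are applied greedily in line-id
#' order; a line whose exclusion would empty the interval is quarantined as
#' a conflict rather than applied, and the result escalates to `conflicted`
#' when more than `ceiling(epsilon * n)` lines are quarantined.
#'
#' Following the two-stage protocol, only lines recombinant between the
#' anchor markers (groups 1 and 2) enter the exclusion stage by default:
#' nonrecombinant lines are excluded from the subsequent assays and their
#' internal genotypes, if any, are ignored. Set `recombinants_only = FALSE`
#' to use every phenotyped line.
#'
#' @param cohort An `f2_cohort`.
#' @param panel The matching [snp_panel()].
#' @param arm The [arm_model()].
#' @param epsilon Tolerated fraction of quarantined lines (default 0.05).
#' @param recombinants_only Restrict exclusions to anchor-recombinant lines
#'   (default TRUE).
#' @return Object of class `mapped_result`: `interval_bp` (convex hull of
#'   the unexcluded region, half-open), `remaining_regions`,
#'   `interval_bands`, `group_counts`, `direction`, `exclusions`,
#'   `conflicts`, `remaining_informative`, `status`.
#' @export
exclusion_map <- function(cohort, panel, arm, epsilon = 0.05,
                          recombinants_only = TRUE) {
  classes <- classify_recombinants(cohort, panel)
  o <- order(cohort$lines$line_id)
  if (recombinants_only)
    o <- o[classes[o] %in% c("group1_distal_mut", "group2_proximal_mut")]
  ids <- cohort$lines$line_id[o]
  phen <- cohort$lines$phenotype[o]
  segs <- lapply(o, function(i)
    infer_segments(cohort$calls[i, ], panel, arm))
  names(segs) <- ids

  remaining <- iv(0, arm$length_bp)
  exclusions <- list()
  conflicts <- character(0)
  used <- 0L
  for (i in seq_along(ids)) {
    ph <- phen[i]
    if (!(ph %in% c("mutant", "weak", "wild_type"))) next
    if (!segs[[i]]$informative) next
    excl <- if (ph == "wild_type") segs[[i]]$certainly_mut
            else segs[[i]]$certainly_map
    used <- used + 1L
    if (iv_width(excl) == 0) next
    rule <- if (ph == "wild_type")
      "wild_type line cannot carry the lesion on mutagenized-origin sequence"
    else "mutant line cannot owe its phenotype to mapping-origin sequence"
    candidate <- iv_setdiff(remaining, excl)
    if (iv_width(candidate) == 0) {
      conflicts <- c(conflicts, ids[i])
    } else {
      remaining <- candidate
      exclusions[[ids[i]]] <- list(intervals = excl, rule = rule)
    }
  }

  status <- if (length(conflicts) > ceiling(epsilon * max(used, 1L)))
    "conflicted" else "consistent"
  hull <- iv_hull(remaining)
  dir <- stage1_direction(classes, cohort$lines$phenotype)
  rem_inf <- ids[vapply(seq_along(ids), function(i) {
    g <- segs[[i]]$gaps
    nrow(g) > 0L && any(g$start_bp < hull[1, 2] & g$end_bp > hull[1, 1])
  }, logical(1))]

  structure(list(
    interval_bp = if (status == "consistent")
      c(start_bp = unname(hull[1, 1]), end_bp = unname(hull[1, 2])) else NULL,
    remaining_regions = remaining,
    interval_bands = if (status == "consistent")
      c(left = bp_to_band(arm, hull[1, 1]),
        right = bp_to_band(arm, hull[1, 2] - 1)) else NULL,
    group_counts = list(group1 = dir$group1, group2 = dir$group2,
                        group3 = c(mutant = sum(
                          classes == "group3_nonrecombinant" &
                            cohort$lines$phenotype %in% c("mutant", "weak")),
                          total = sum(classes == "group3_nonrecombinant"))),
    direction = dir$direction,
    exclusions = exclusions,
    conflicts = conflicts,
    remaining_informative = rem_inf,
    n_informative_recombinants = sum(classes %in%
      c("group1_distal_mut", "group2_proximal_mut")),
    status = status,
    arm_name = arm$name),
    class = "mapped_result")
}

#' @export
print.mapped_result <- function(x, ...) {
  cat(format_mapping_summary(x), sep = "\n")
  invisible(x)
}

#' Brute-force consistency oracle over a position grid
#'
#' Independent check of the exclusion mapper: a grid position is retained
#' iff placing the lesion there reproduces every line's phenotype given its
#' certain origin segments (positions inside uncertainty gaps are
#' unconstrained). On conflict-free data the convex hull of the retained
#' set equals the exclusion-mapped interval.
#'
#' @inheritParams exclusion_map
#' @param grid_step Grid spacing in bp.
#' @return Numeric vector of retained grid positions.
#' @export
brute_force_consistency <- function(cohort, panel, arm, grid_step = 10000,
                                    recombinants_only = TRUE) {
  stopifnot(grid_step > 0)
  classes <- classify_recombinants(cohort, panel)
  grid <- seq(0, arm$length_bp - 1, by = grid_step)
  ok <- rep(TRUE, length(grid))
  for (i in seq_len(nrow(cohort$calls))) {
    if (recombinants_only &&
        !(classes[i] %in% c("group1_distal_mut", "group2_proximal_mut")))
      next
    ph <- cohort$lines$phenotype[i]
    if (!(ph %in% c("mutant", "weak", "wild_type"))) next
    s <- infer_segments(cohort$calls[i, ], panel, arm)
    if (!s$informative) next
    forbidden <- if (ph == "wild_type") s$certainly_mut else s$certainly_map
    if (nrow(forbidden) == 0L) next
    for (j in seq_len(nrow(forbidden)))
      ok <- ok & !(grid >= forbidden[j, 1] & grid < forbidden[j, 2])
  }
  grid[ok]
}
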