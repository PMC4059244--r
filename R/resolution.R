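#' Run one simulated screen end to end
#'
#' Chains lesion simulation, F2 cohort construction, exclusion mapping and
#' candidate annotation for a single replicate, and compares the mapped
#' result against the hidden truth.
#'
#' @param config A [sim_config()].
#' @param arm An [arm_model()].
#' @param genes A [gene_model()] with sequences.
#' @param panel An [snp_panel()].
#' @param seed Integer seed for this replicate.
#' @param annotate Classify candidates inside the mapped interval
#'   (default TRUE; skip for speed when only the interval matters).
#' @return One-row data.frame (`screen_outcome`): interval length,
#'   truth coverage, candidate and recombinant counts, mapper status, seed.
#' @export
run_screen <- function(config, arm, genes, panel, seed = config$seed,
                       annotate = TRUE) {
  set.seed(seed)
  mut <- simulate_lesions(arm, genes, config)
  cohort <- make_f2_cohort(mut, panel, arm, genes, config)
  res <- exclusion_map(cohort, panel, arm)
  caus_pos <- mut$lesions$position_bp[mut$lesions$id %in% mut$causative_ids]
  contains <- if (res$status == "consistent")
    all(vapply(caus_pos, function(p)
      iv_contains_point(res$remaining_regions, p), logical(1)))
  else NA
  n_cand <- NA_integer_
  if (annotate && res$status == "consistent") {
    cand <- candidates_in_interval(mut$lesions, res$interval_bp, genes)
    n_cand <- sum(!is.na(cand$rank))
  }
  data.frame(
    interval_length_bp = if (res$status == "consistent")
      res$interval_bp[["end_bp"]] - res$interval_bp[["start_bp"]] else NA_real_,
    contains_truth = contains,
    n_candidates = n_cand,
    n_informative_recombinants = res$n_informative_recombinants,
    n_recombinant_products = sum(vapply(cohort$truth$breakpoints, length,
                                        integer(1)) > 0),
    n_remaining_informative = length(res$remaining_informative),
    status = res$status,
    seed = seed)
}

#' Monte-Carlo resolution study
#'
#' Replicates [run_screen()] with per-replicate seeds drawn once from a
#' master seed.
#'
#' @inheritParams run_screen
#' @param n_reps Number of replicate screens.
#' @param master_seed Master seed from which per-replicate seeds derive.
#' @return Data.frame of per-replicate `screen_outcome` rows.
#' @export
run_resolution <- function(config, arm, genes, panel, n_reps = 500L,
                           master_seed = 1L, annotate = TRUE) {
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max - 1L, n_reps))
  do.call(rbind, lapply(seeds, function(s)
    run_screen(config, arm, genes, panel, seed = s, annotate = annotate)))
}

#' Summarize a set of screen outcomes
#'
#' Deterministic summary of a resolution study, with the order-statistics
#' reference curve `E[interval] ~ 2L / (k + 1)` for `k` informative
#' recombinants as a closed-form comparison.
#'
#' @param outcomes Data.frame from [run_resolution()].
#' @param arm The [arm_model()] used (for the closed-form reference);
#'   optional.
#' @return List of class `resolution_summary`.
#' @export
summarize_outcomes <- function(outcomes, arm = NULL) {
  if (nrow(outcomes) == 0L) stop("no outcomes to summarize")
  ok <- outcomes$status == "consistent"
  qs <- stats::quantile(outcomes$interval_length_bp[ok],
                        c(.05, .25, .5, .75, .95), na.rm = TRUE)
  med_k <- stats::median(
    if ("n_recombinant_products" %in% names(outcomes))
      outcomes$n_recombinant_products
    else outcomes$n_informative_recombinants)
  structure(list(
    n_reps = nrow(outcomes),
    interval_quantiles_bp = qs,
    median_interval_bp = unname(qs[[3]]),
    median_candidates = stats::median(outcomes$n_candidates[ok], na.rm = TRUE),
    candidate_table = table(outcomes$n_candidates[ok]),
    coverage = mean(outcomes$contains_truth[ok], na.rm = TRUE),
    fraction_conflicted = mean(outcomes$status == "conflicted"),
    median_informative_recombinants = med_k,
    closed_form_interval_bp = if (!is.null(arm))
      2 * arm$length_bp / (med_k + 1) else NA_real_),
    class = "resolution_summary")
}

#' @export
print.resolution_summary <- function(x, ...) {
  cat(sprintf("resolution_summary over %d screens\n", x$n_reps))
  cat(sprintf("  median interval: %.2f Mb (closed form 2L/(k+1): %.2f Mb at k=%g)\n",
              x$median_interval_bp / 1e6, x$closed_form_interval_bp / 1e6,
              x$median_informative_recombinants))
  cat(sprintf("  interval quantiles (Mb): %s\n",
              paste(sprintf("%s=%.2f", names(x$interval_quantiles_bp),
                            x$interval_quantiles_bp / 1e6), collapse = " ")))
  cat(sprintf("  median candidates: %g; coverage: %.3f; conflicted: %.3f\n",
              x$median_candidates, x$coverage, x$fraction_conflicted))
  invisible(x)
}
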