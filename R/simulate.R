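#' Screen simulation configuration
#'
#' Defaults reproduce the study conditions of a standard Drosophila mosaic
#' screen: a 25 mM EMS dose inducing one mutation per 400 kb, 48 F2
#' recombinant lines, and a crossover rate given by the arm's genetic length
#' (0.47 expected crossovers per meiosis for a 47 cM arm).
#'
#' @param lesion_rate_per_bp EMS lesion rate per bp (default 1/400000).
#' @param n_f2_lines Number of F2 recombinant lines genotyped (default 48).
#' @param crossover_mean Expected crossovers per meiosis; `NULL` (default)
#'   means `genetic_length_cM / 100` of the arm in use.
#' @param phenotyping_error Probability a line's germline-clone phenotype is
#'   scored wrongly (default 0).
#' @param genotype_fail_rate Probability a SNP call fails (default 0).
#' @param genotype_miscall_rate Probability a SNP call reports the wrong
#'   parent (default 0).
#' @param seed Integer seed recorded in all outputs.
#' @param two_locus `NULL`, or `list(distal_bp =, proximal_bp =)` for a
#'   synthetic two-locus phenotype: lines carrying both mutagenized-origin
#'   loci score `mutant` (strong), the distal locus alone `weak`, otherwise
#'   `wild_type`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(lesion_rate_per_bp = 1 / 400000, n_f2_lines = 48L,
                       crossover_mean = NULL, phenotyping_error = 0,
                       genotype_fail_rate = 0, genotype_miscall_rate = 0,
                       seed = 1L, two_locus = NULL) {
  stopifnot(lesion_rate_per_bp >= 0, n_f2_lines >= 1,
            phenotyping_error >= 0, phenotyping_error <= 1,
            genotype_fail_rate >= 0, genotype_fail_rate <= 1,
            genotype_miscall_rate >= 0, genotype_miscall_rate <= 1)
  if (!is.null(two_locus))
    stopifnot(is.list(two_locus),
              all(c("distal_bp", "proximal_bp") %in% names(two_locus)),
              two_locus$distal_bp < two_locus$proximal_bp)
  structure(list(lesion_rate_per_bp = lesion_rate_per_bp,
                 n_f2_lines = as.integer(n_f2_lines),
                 crossover_mean = crossover_mean,
                 phenotyping_error = phenotyping_error,
                 genotype_fail_rate = genotype_fail_rate,
                 genotype_miscall_rate = genotype_miscall_rate,
                 seed = as.integer(seed), two_locus = two_locus),
            class = "sim_config")
}

config_crossover_mean <- function(config, arm) {
  config$crossover_mean %||% (arm$genetic_length_cM / 100)
}

#' Simulate EMS lesions on a mutagenized chromosome arm
#'
#' Draws a Poisson number of lesions (`length_bp * lesion_rate_per_bp`
#' expected) at uniform positions, with the EMS substitution spectrum
#' (G/C sites mutate to A/T by transition with probability 0.9, otherwise
#' uniformly; A/T sites uniformly). Reference alleles are taken from gene
#' sequences where a lesion falls inside a gene span, and drawn at random
#' elsewhere. Exactly one lesion with a protein-coding consequence is
#' flagged causative; the draw is repeated (up to `max_resample` times) if
#' no lesion qualifies.
#'
#' Uses R's global random number generator; seed it with the config's seed
#' before calling for reproducible screens.
#'
#' @param arm An [arm_model()].
#' @param genes A [gene_model()] with sequences.
#' @param config A [sim_config()].
#' @param inject Optional lesion data.frame appended to the random draw
#'   (its qualifying rows join the causative draw).
#' @param max_resample Resampling bound when no qualifying lesion arises.
#' @return Object of class `mut_chromosome`: `lesions` (classified lesion
#'   table) and `causative_ids`.
#' @export
simulate_lesions <- function(arm, genes, config, inject = NULL,
                             max_resample = 100L) {
  for (try in seq_len(max_resample)) {
    n <- stats::rpois(1L, arm$length_bp * config$lesion_rate_per_bp)
    pos <- if (n > 0) sort(sample.int(arm$length_bp, n) - 1) else numeric(0)
    ref <- ref_base_at(genes, pos)
    alt <- ems_alt(ref)
    les <- data.frame(id = sprintf("sim%03d", seq_len(n))[seq_len(n)],
                      position_bp = pos, kind = rep("snv", n),
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
    if (!is.null(inject)) les <- rbind(les, inject[names(les)])
    if (nrow(les) == 0L) next
    les <- les[order(les$position_bp), , drop = FALSE]
    ann <- classify_effects(les, genes)
    qual <- which(is_coding_candidate(ann))
    if (length(qual) >= 1L) {
      causative <- ann$id[qual[sample.int(length(qual), 1L)]]
      return(structure(list(lesions = ann, causative_ids = causative),
                       class = "mut_chromosome"))
    }
  }
  stop("no lesion with a coding consequence after ", max_resample,
       " draws; increase the lesion rate, arm length or coding fraction")
}

ref_base_at <- function(genes, pos) {
  n <- length(pos)
  if (n == 0L) return(character(0))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  gi <- findInterval(pos, genes$start)
  inside <- gi >= 1L & pos < genes$end[pmax(gi, 1L)]
  for (i in which(inside)) {
    b <- gene_base(genes$genes[[gi[i]]], pos[i])
    if (!is.na(b)) ref[i] <- toupper(b)
  }
  ref
}

## EMS spectrum: G->A / C->T transitions with probability 0.9 at G/C sites.
ems_alt <- function(ref) {
  n <- length(ref)
  if (n == 0L) return(character(0))
  alt <- character(n)
  transition <- stats::runif(n) < 0.9 & ref %in% c("G", "C")
  alt[transition] <- ifelse(ref[transition] == "G", "A", "T")
  for (i in which(!transition))
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
  alt
}

#' Simulate one meiosis on the F1 female
#'
#' Crossover count is Poisson with mean `crossover_mean`; positions are
#' i.i.d. uniform on the arm (no chiasma interference).
#'
#' @param arm An [arm_model()].
#' @param crossover_mean Expected crossovers per meiosis.
#' @return Sorted numeric vector of crossover positions (possibly empty).
#' @export
simulate_meiosis <- function(arm, crossover_mean) {
  stopifnot(crossover_mean >= 0)
  k <- stats::rpois(1L, crossover_mean)
  sort(stats::runif(k, 0, arm$length_bp))
}

## Parent of origin at positions x given breakpoints and starting parent.
origin_at <- function(x, breakpoints, start_parent) {
  other <- if (start_parent == "MUT") "MAP" else "MUT"
  ifelse(findInterval(x, breakpoints) %% 2 == 0, start_parent, other)
}

#' Simulate an F2 recombinant cohort
#'
#' Each line derives from one meiotic product of the F1 female
#' (mutagenized chromosome over the SNP-marked mapping chromosome):
#' parent-of-origin alternates across the line's crossovers starting from a
#' random parent. The germline-clone phenotype is `mutant` iff the product
#' carries a causative lesion on mutagenized-origin sequence (or follows the
#' configured two-locus rule), mis-scored with probability
#' `phenotyping_error`. SNP calls report the true origin at each panel
#' locus, set to `FAIL` with `genotype_fail_rate` and flipped with
#' `genotype_miscall_rate`.
#'
#' Uses R's global random number generator.
#'
#' @param mut A `mut_chromosome` from [simulate_lesions()] (ignored in
#'   two-locus mode, where the configured loci define the phenotype).
#' @param panel An [snp_panel()].
#' @param arm An [arm_model()].
#' @param genes A [gene_model()] (recorded for provenance; not used here).
#' @param config A [sim_config()].
#' @return Object of class `f2_cohort`: `lines` (line_id, phenotype),
#'   `calls` (lines x SNPs character matrix of MUT/MAP/FAIL), and `truth`
#'   (hidden breakpoints and starting parents, simulation only).
#' @export
make_f2_cohort <- function(mut, panel, arm, genes = NULL, config) {
  if (nrow(panel$loci) == 0L) stop("empty SNP panel")
  n <- config$n_f2_lines
  m <- nrow(panel$loci)
  pos <- panel$loci$position_bp
  cm <- config_crossover_mean(config, arm)
  caus_pos <- if (!is.null(mut))
    mut$lesions$position_bp[mut$lesions$id %in% mut$causative_ids]
  else numeric(0)
  calls <- matrix("", n, m,
                  dimnames = list(sprintf("F2_%02d", seq_len(n)),
                                  panel$loci$snp_id))
  phen <- character(n)
  bks <- vector("list", n)
  starts <- character(n)
  for (i in seq_len(n)) {
    bk <- simulate_meiosis(arm, cm)
    sp <- sample(c("MUT", "MAP"), 1L)
    bks[[i]] <- bk; starts[i] <- sp
    if (is.null(config$two_locus)) {
      carries <- length(caus_pos) > 0 &&
        any(origin_at(caus_pos, bk, sp) == "MUT")
      ph <- if (carries) "mutant" else "wild_type"
    } else {
      cA <- origin_at(config$two_locus$distal_bp, bk, sp) == "MUT"
      cB <- origin_at(config$two_locus$proximal_bp, bk, sp) == "MUT"
      ph <- if (cA && cB) "mutant" else if (cA) "weak" else "wild_type"
    }
    if (config$phenotyping_error > 0 &&
        stats::runif(1) < config$phenotyping_error)
      ph <- if (ph == "wild_type") "mutant" else "wild_type"
    phen[i] <- ph
    v <- origin_at(pos, bk, sp)
    if (config$genotype_miscall_rate > 0) {
      flip <- stats::runif(m) < config$genotype_miscall_rate
      v[flip] <- ifelse(v[flip] == "MUT", "MAP", "MUT")
    }
    if (config$genotype_fail_rate > 0)
      v[stats::runif(m) < config$genotype_fail_rate] <- "FAIL"
    calls[i, ] <- v
  }
  structure(list(
    lines = data.frame(line_id = rownames(calls), phenotype = phen,
                       stringsAsFactors = FALSE),
    calls = calls,
    truth = list(breakpoints = bks, start_parent = starts),
    seed = config$seed),
    class = "f2_cohort")
}

#' @export
print.f2_cohort <- function(x, ...) {
  cat(sprintf("f2_cohort: %d lines x %d SNPs (%s)\n", nrow(x$calls),
              ncol(x$calls),
              paste(sprintf("%s=%d", names(table(x$lines$phenotype)),
                            table(x$lines$phenotype)), collapse = ", ")))
  invisible(x)
}
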