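#' Detect a two-locus synthetic phenotype
#'
#' Searches ordered pairs of inter-marker gaps (A distal, B proximal) under
#' the synthetic-phenotype rule: carrying the mutagenized-origin allele at
#' both loci gives the strong (`mutant`) phenotype, at A alone the `weak`
#' phenotype, otherwise `wild_type`. Carriage of a gap is certain only when
#' both flanking markers agree (and did not fail); lines whose carriage is
#' uncertain at a tested locus cannot be falsified and count as explained.
#' The best two-locus consistency score is compared with the best
#' single-locus score (lesion in a single gap, weak never predicted); a
#' two-locus hypothesis is recommended only when it explains at least
#' `margin` more lines, penalizing the extra degree of freedom.
#'
#' @inheritParams exclusion_map
#' @param margin Minimum improvement (explained lines) over the best
#'   single-locus placement (default 3).
#' @return List: `applicable`, `n_lines`, `score1`, `n_explained1`,
#'   `score2`, `n_explained2`, `two_locus_suspected`, `best_pairs`
#'   (data.frame of gap bp bounds for every maximal pair), `margin`.
#' @export
detect_two_locus <- function(cohort, panel, arm, margin = 3L) {
  pos <- panel$loci$position_bp
  m <- length(pos)
  n <- nrow(cohort$calls)
  ph <- cohort$lines$phenotype
  if (m < 3L || all(ph == "wild_type"))
    return(list(applicable = FALSE, n_lines = n,
                two_locus_suspected = FALSE, margin = margin))

  ## carriage per line per inter-marker gap: 1 = carries, 0 = not, NA = unknown
  G <- m - 1L
  carr <- matrix(NA, n, G)
  for (j in seq_len(G)) {
    l <- cohort$calls[, j]; r <- cohort$calls[, j + 1L]
    carr[, j] <- ifelse(l == "MUT" & r == "MUT", 1,
                 ifelse(l == "MAP" & r == "MAP", 0, NA))
  }

  ## single-locus: predicted mutant iff carried; weak observations are
  ## never explained by a determinate single-locus prediction
  expl1 <- vapply(seq_len(G), function(j) {
    cj <- carr[, j]
    sum(is.na(cj) | (cj == 1 & ph == "mutant") |
          (cj == 0 & ph == "wild_type"))
  }, numeric(1))
  n1 <- max(expl1)

  ## two-locus: dedupe identical carriage columns before the pair scan
  key <- apply(carr, 2, paste, collapse = "/")
  uniq <- !duplicated(key)
  ucols <- which(uniq)
  uidx <- match(key, key[uniq])  # gap -> unique pattern
  explained_pair <- function(cA, cB) {
    okA1 <- is.na(cA) | cA == 1  # A may be carried
    okA0 <- is.na(cA) | cA == 0  # A may be absent
    okB1 <- is.na(cB) | cB == 1
    okB0 <- is.na(cB) | cB == 0
    can_mut <- okA1 & okB1
    can_weak <- okA1 & okB0
    can_wt <- okA0
    sum((ph == "mutant" & can_mut) | (ph == "weak" & can_weak) |
        (ph == "wild_type" & can_wt))
  }
  U <- length(ucols)
  score <- matrix(-1, U, U)
  for (a in seq_len(U)) for (b in seq_len(U)) {
    ## ordered pair must be realizable with gap index a' < b'
    ga <- which(uidx == a); gb <- which(uidx == b)
    if (min(ga) >= max(gb)) next
    score[a, b] <- explained_pair(carr[, ucols[a]], carr[, ucols[b]])
  }
  n2 <- max(score)
  best <- which(score == n2, arr.ind = TRUE)
  pairs <- do.call(rbind, lapply(seq_len(nrow(best)), function(i) {
    a <- best[i, 1]; b <- best[i, 2]
    ga <- which(uidx == a); gb <- which(uidx == b)
    eg <- expand.grid(A = ga, B = gb)
    eg <- eg[eg$A < eg$B, , drop = FALSE]
    data.frame(gapA_start = pos[eg$A], gapA_end = pos[eg$A + 1L],
               gapB_start = pos[eg$B], gapB_end = pos[eg$B + 1L])
  }))
  list(applicable = TRUE, n_lines = n,
       score1 = n1 / n, n_explained1 = n1,
       score2 = n2 / n, n_explained2 = n2,
       two_locus_suspected = n2 >= n1 + margin,
       best_pairs = pairs, margin = margin)
}
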