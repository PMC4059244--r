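---
title: "Exclusion mapping of EMS-induced mutations in mosaic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exclusion mapping of EMS-induced mutations in mosaic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicmap)
```

# The mapping problem

A germline mosaic screen recovers mutant lines whose causative lesion lies
somewhere on one mutagenized chromosome arm. Each F2 mapping line derives
that arm from a single meiosis between the mutagenized chromosome (MUT)
and a polymorphic mapping chromosome (MAP), so along the arm the line is a
mosaic of MUT- and MAP-derived blocks separated by crossover breakpoints.
Genotyping a line at a SNP marker reveals the parental origin of that
position; its phenotype reveals whether a MUT-derived block covers the
lesion. `mosaicmap` implements the resulting two-stage exclusion-mapping
protocol, the intersection of a whole-genome lesion list with the mapped
interval, a detector for two-locus synthetic phenotypes, and a simulator
that generates the whole experiment so each stage can be tested against a
known truth.

Coordinates are 0-based half-open throughout the package, with the distal
end (telomere) at 0 and the proximal end (centromere/FRT side) at the arm
length; VCF and GFF3 files are 1-based on disk and converted only in the
I/O layer.

# The meiosis and mutagenesis model

A single meiosis is modeled as a Poisson number of crossovers with mean
equal to the arm's genetic length in Morgans (default 47 cM, hence mean
0.47 per product for the 23 Mb arm the defaults describe), with crossover
positions uniform on the arm and no interference. Under this model the
recombination fraction between two loci separated by `d` Morgans is the
Haldane map function `(1 - exp(-2d))/2`, which the test suite checks by
simulation. Each F2 line draws one product and, independently and with
equal probability, whether the arm distal of position zero starts on the
MUT or MAP parent; parental origin at any position then alternates across
breakpoints.

Mutagenesis places lesions as a Poisson process at
`lesion_rate_per_bp = 1/400000` (one EMS lesion per 400 kb at standard
dosing), with the EMS spectrum approximated as 90% G/C-to-A/T transitions
at G/C sites. The synthetic gene model covers ~22% of the arm with coding
exons (`coding_fraction = 0.22`); with roughly three quarters of random
coding SNVs having a protein-level consequence, this calibrates the
simulator to ~10 qualifying coding lesions per mutagenized arm, matching
the density the protocol is designed around. One qualifying lesion is
designated causative; a simulated screen whose lesion draw contains no
qualifying lesion is redrawn (the screen could not have produced a mutant
line).

# Two-stage exclusion mapping

**Stage 1.** Every line is genotyped at two *anchor* SNPs near the arm
ends. Lines whose anchors derive from different parents are recombinant:
group 1 (distal MUT / proximal MAP), group 2 (the reverse); lines with
concordant anchors are group 3 (nonrecombinant) and are excluded from the
subsequent assays, since their breakpoints (if any) cannot be bracketed by
the anchors. The mutant fraction within groups 1 and 2 gives the map
direction: if group 2 recombinants are mostly mutant the lesion lies
nearer the proximal anchor. `weak` phenotypes count as mutant here.

**Stage 2.** Recombinant lines are genotyped across the internal panel.
For one line, maximal runs of identical non-failed calls are *certain*
segments; a run is closed at its outermost markers and a terminal run
extends to the arm end on its side (no marker beyond it can contradict
it). Between two runs of different origin lies an *uncertainty gap*
bounded by the flanking informative markers; failed calls simply widen
gaps. The logic of exclusion is:

* a **wild-type** line cannot carry the lesion on any certainly
  MUT-derived segment — those segments are excluded;
* a **mutant** (or weak) line cannot owe its phenotype to MAP-derived
  sequence — its certainly MAP segments are excluded.

The mapped region is the arm minus the union of exclusions; its convex
hull is reported with cytological band endpoints. This closure is
deliberately conservative: exclusions stop at genotyped markers, never
extrapolate into uncertainty gaps, so the causative lesion can never be
excluded by an error-free line. The test suite verifies this soundness
property over a thousand simulated screens, and verifies equivalence with
an independent brute-force oracle that retains every grid position whose
hypothetical lesion placement reproduces all phenotypes.

Restricting stage 2 to anchor-recombinant lines is part of the protocol,
not merely an economy: it reflects what is actually genotyped, and it sets
the expected resolution. The expected interval from `k` breakpoints
uniform on an arm of physical length `L` is `E[interval] ≈ 2L/(k+1)` by
order statistics, about 2.4 Mb for a 48-line screen at 0.47 crossovers per
product — the 2–3 Mb regime the protocol targets. `exclusion_map(...,
recombinants_only = FALSE)` is available when every line has been
genotyped everywhere; it roughly halves the interval in simulation but
does not correspond to the two-stage assay. The Monte-Carlo study
(`run_resolution`) reports the measured median against the closed form.

**Conflicts.** Real data contain phenotyping and genotyping errors, so an
exclusion can contradict the rest of the cohort. Exclusions are applied
greedily in line-id order; a line whose exclusion would empty the region
is quarantined rather than applied, and when more than
`ceiling(epsilon * n)` of the `n` usable lines are quarantined
(`epsilon = 0.05`) the result is declared `conflicted` and no interval is
reported. Greedy quarantine keeps the procedure deterministic and
attributes each conflict to a specific line for follow-up; it does not
attempt a maximum-consistency search.

# Candidate intersection

`candidates_in_interval` classifies each lesion of a whole-genome lesion
list against the gene models (codon-level translation for SNVs via the
standard genetic code, strand-aware; 2 bp splice edges; frameshift by
deletion length mod 3; insertions in a gene body as disruptions) and ranks
the coding candidates inside the mapped interval: truncating classes
(nonsense, stop-lost, splice-site, frameshift, insertion disruption)
before missense before in-frame deletions, ties broken distal-first.
Lesions whose stated reference allele contradicts the gene model are kept
but ranked last and flagged — on real data these are usually annotation or
alignment artifacts, and silently dropping them would hide evidence.
`shared_mutated_genes` supports allelism-by-sequence: genes with
qualifying lesions in each of two independently induced lines.

# Two-locus phenotypes

Some screens produce lines whose phenotype needs two loci: *strong* when
the line carries MUT-derived sequence at both, *weak* with the distal
locus alone. `detect_two_locus` scores every ordered pair of inter-marker
gaps under that rule, calling carriage of a gap certain only when both
flanking markers agree; lines whose carriage is unknown at a tested locus
cannot be falsified and count as explained (an intentionally optimistic
convention — it keeps the true pair at score 1.0 on error-free data). The
best pair must explain at least `margin = 3` more lines than the best
single-locus placement before a two-locus model is recommended; the margin
pays for the extra degree of freedom, so screens with zero or one weak
line never fire. Duplicate carriage columns are collapsed before the
quadratic pair scan.

# The simulator as the test harness

`simulate_lesions`, `make_f2_cohort` and `run_screen` generate the
experiment end to end: lesions with classified effects and a designated
causative one, per-line breakpoints and start parents (retained as hidden
truth), genotype calls with configurable per-call failure
(`genotype_fail_rate`) and miscall (`genotype_miscall_rate`) rates, and
phenotypes with a configurable misscoring probability
(`phenotyping_error`). All defaults are the study conditions: 23 Mb arm,
47 cM, 48 F2 lines, 1 SNP per 1.5 kb, error rates zero. Every stochastic
function consumes the R RNG, so a `sim_config` plus a seed reproduces a
cohort byte for byte; `run_resolution` draws per-replicate seeds once from
a master seed.

The generator emulates the features the mapping logic depends on —
block-wise parental origin, marker informativity, lesion density and
spectrum, coding effects on synthetic gene structures — and deliberately
not the features it does not: no crossover interference or centromere
suppression, uniform marker informativity (every SNP separates the
parents), a uniform gene landscape rather than real gene annotation,
phenotyping error as symmetric misscoring, and no population-level
structure across lines. Passing tests therefore demonstrate correctness
of the inference given the model, and calibration of resolution against
breakpoint counts; they do not demonstrate robustness to non-uniform
recombination or marker dropout structure in real material.

Problem sizes in the test suite and analysis scripts are the package's
own choices: the deterministic 48-line worked example; 500 replicate
screens at the full 1/1.5 kb panel for the resolution study; 1,000
error-free screens and a 200-cohort oracle comparison on a 1/50 kb panel
for the property checks; 200 single-locus replicates on a 1/250 kb panel
for the two-locus false-positive rate.

# The bundled worked example

`make_11R2_fixture()` constructs, deterministically, a 48-line cohort
whose group structure reproduces the canonical published cross this
protocol comes from: 19 recombinants (13 group 1 of which 3 mutant, 6
group 2 of which 5 mutant), direction proximal, mapped interval 66F–69C
with exactly 4 recombinants retaining breakpoints inside it, and a lesion
list whose intersection with the interval leaves one ranked candidate — a
nonsense mutation (Q33>stop, CAG→TAG) in band 67D of a *nudE*-like gene.
The same cohort, panel, band table and lesion list ship as plain-text
files under `inst/extdata/` and are read back through the package's own
parsers in the tests.

```{r worked-example}
fx <- make_11R2_fixture()
m <- exclusion_map(fx$cohort, fx$panel, fx$arm)
m
head(candidates_in_interval(fx$lesions, m$interval_bp, fx$genes)[,
  c("id", "position_bp", "effect_class", "protein_change", "rank")], 3)
```

# Degenerate inputs and numerical conventions

* An all-failed genotype row is uninformative and contributes nothing.
* A cohort with no informative recombinant returns the whole arm.
* Band tables must tile the arm exactly; the default synthetic table cuts
  the arm into 120 equal bands labelled 61A–80F.
* Genotype CSVs degrade unknown call tokens to `FAIL` and unknown
  phenotype tokens to `unknown`, each with a warning, rather than erroring
  on a single bad cell.
* Deletions and insertions in VCF use an anchor base (`N` when unknown);
  insertions of a named element are written as symbolic `<INS:ME:label>`.
* Seeds are plain R integers (< 2^31); manifests record the config, an
  FNV-1a hash of its canonical JSON, the package version and input MD5s.

# Known limitations

The resolution claim is conditional on the no-interference Poisson model;
real interference slightly reduces double crossovers and so changes the
high quantiles of interval length. The conflict handler quarantines
greedily rather than searching for a maximum consistent subset, so with
clustered errors the reported interval can depend on line ordering. The
two-locus search considers exactly two loci with the weak = distal-only
rule; other epistasis patterns require a different phenotype map.
Cytological bands here are synthetic equal-width tiles, not real banding
coordinates.
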