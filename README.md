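# mosaicmap

Identify EMS-induced causative mutations in *Drosophila* germline mosaic
screens by SNP recombination exclusion mapping.

A mosaic screen recovers mutant lines whose lesion lies somewhere on one
mutagenized chromosome arm. Each F2 mapping line inherits that arm from a
single meiosis between the mutagenized chromosome (MUT) and a polymorphic
mapping chromosome (MAP), so the arm is a mosaic of MUT- and MAP-derived
blocks. Genotyping a SNP reveals the parental origin of that position;
the phenotype reveals whether a MUT block covers the lesion. `mosaicmap`
implements the analysis this geometry allows, together with a simulator
of the whole experiment so every inference step can be tested against a
known truth:

* **Two-stage exclusion mapping.** Stage 1 classifies lines by two anchor
  SNPs near the arm ends: group 1 (distal MUT / proximal MAP), group 2
  (the reverse), group 3 (nonrecombinant, dropped from further assays);
  the mutant fraction per group gives the map direction. Stage 2
  genotypes recombinants across a dense internal panel and excludes, for
  each line, the regions whose certain parental origin contradicts its
  phenotype: a wild-type line excludes its certainly-MUT segments, a
  mutant line its certainly-MAP segments. The unexcluded remainder, with
  cytological band endpoints, is the mapped interval.
* **Candidate intersection.** A whole-genome lesion list (VCF) is
  classified against gene models (nonsense/missense/splice/frameshift,
  strand-aware codon translation) and ranked inside the interval,
  truncating classes first.
* **Two-locus phenotypes.** A consistency search over pairs of
  inter-marker gaps detects weak/strong synthetic phenotypes (weak =
  distal locus only, strong = both).
* **Monte-Carlo resolution.** Simulated screens (Poisson crossovers at
  the arm's genetic length, Poisson EMS lesions at 1/400 kb, ~10 coding
  lesions per arm) measure interval length, truth coverage and candidate
  yield against the order-statistics closed form `E[interval] ≈ 2L/(k+1)`
  for `k` recombinant products on an arm of length `L`.

## Worked example

The bundled 48-line fixture reproduces the canonical cross this protocol
was built on (plain-text copies of the genotype table, SNP panel, band
table and lesion VCF are under `inst/extdata/`). Running
`Rscript analysis/01_worked_example.R` prints:

```
exclusion mapping on arm 3L: status consistent
  groups (mutant/total): 1 distal-mut 3/13; 2 proximal-mut 5/6; 3 nonrecombinant 14/29
  stage-1 direction: lesion nearer the proximal anchor
  interval: 66F-69C (6816001-9696000 bp, 2.88 Mb)
  4 recombinant(s) retain breakpoints inside the interval; 0 conflict(s)

19/48 lines recombinant (13 group 1, 6 group 2); direction proximal
interval 66F-69C; 1 ranked candidate(s): nudE_like Q33>stop
```

Reading: of 48 phenotyped lines, 19 are recombinant between the anchors;
3/13 group-1 versus 5/6 group-2 mutants place the lesion toward the
proximal (centromere-side) anchor; exclusion over the internal SNPs of
the 19 recombinants narrows it to bands 66F–69C (2.88 Mb), with 4
recombinants still carrying a breakpoint inside the interval; and
intersecting the lesion list with that interval leaves exactly one
ranked coding candidate, a nonsense mutation (Q33>stop) in a *nudE*-like
gene at band 67D.

## The analysis workflow

Numbered drivers under `analysis/` write their tables under `results/`:

* `01_worked_example.R` — the deterministic mapping above
  (`worked_example_groups.csv`, `worked_example_mapping.json`,
  `worked_example_candidates.csv`).
* `02_resolution_study.R` — 500 simulated screens at study defaults
  (23 Mb arm, 47 cM, 48 lines, 1 SNP/1.5 kb, error-free) plus a
  cohort-size sweep. Printed on this machine:

  ```
  resolution_summary over 500 screens
    median interval: 2.26 Mb (closed form 2L/(k+1): 2.42 Mb at k=18)
    interval quantiles (Mb): 5%=0.47 25%=1.27 50%=2.26 75%=3.37 95%=6.02
    median candidates: 2; coverage: 1.000; conflicted: 0.000
  ```

  The median mapped interval sits in the 2–3 Mb regime the protocol
  targets, within 7% of the closed form at the measured median of 18
  recombinant products; the causative lesion is never excluded
  (coverage 1.000) and the median screen retains 2 coding candidates.
* `03_two_locus_study.R` — two-locus detection: on simulated weak/strong
  cohorts the best gap pair contained both true loci in 30/30 replicates
  (and the call fired in all 14 replicates with ≥5 weak lines); on 100
  single-locus cohorts it never fired.

All computation lives in the package under `R/`; the scripts are thin
drivers over exported functions.

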