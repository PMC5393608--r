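---
title: "Evaluating DNA barcodes: discrimination criteria, supermatrices, and misidentification screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BarcodeEval)
```

## The problem

Plant groups with poor morphological separation between species -- the
laurels are the canonical example, with hundreds of rainforest tree species
that are routinely sterile when collected -- are identified in practice
from short standardized DNA regions: the plastid barcodes *rbcL*, *matK*
and *trnH--psbA*, and the nuclear ribosomal ITS region (or its ITS2
subunit). Two questions recur in every barcoding survey of such a group:

1. **How well does each locus, or combination of loci, discriminate the
   sampled species and genera?**
2. **Which individual specimens were misidentified in the field or the
   herbarium?** Sequence data places a specimen among its true relatives
   regardless of what name is on the voucher, so a well-sampled barcode
   matrix doubles as an error detector for the taxonomy it was labeled
   with.

BarcodeEval implements the two standard evaluation criteria, the
supporting machinery (distances, neighbour-joining with bootstrap,
supermatrix concatenation, simple indel coding, recovery accounting), a
placement-audit workflow for question 2, and a simulator that generates
multi-locus barcode datasets with known truth so the entire pipeline can
be validated end to end.

## Success criteria

**Tree-based (monophyly) criterion.** A neighbour-joining tree is built
from pairwise distances (K2P by default, with pairwise deletion of gaps
and ambiguous sites), and nonparametric bootstrap supports are attached to
its edges by resampling alignment columns. A species succeeds when all of
its sequenced individuals form one side of a bipartition of the unrooted
tree whose edge support is *strictly greater* than the threshold (default
50). The strict comparison follows the usual wording of the criterion
("greater than 50%") even though figures conventionally display supports
"\>= 50". Taxa with a single sequenced individual cannot be tested for
monophyly and are always excluded from tree-based rates (which is why
tree-based analyses are inherently "n >= 2"). The genus criterion is the
species criterion applied one rank up. Because NJ trees are unrooted, the
criterion is evaluated on bipartitions, not rooted clades; on a four-leaf
tree the single internal edge therefore certifies both of the two-leaf
groups it separates.

**Similarity-based (best-hit) criterion.** Every specimen is scored
against every other specimen's gap-stripped sequence by Smith--Waterman
local alignment with blastn-like parameters (match +1, mismatch -2, gap
open 2.5, gap extend 2.5) -- the in-package stand-in for querying a local
BLAST database. A species succeeds when *every* individual's entire
top-scoring hit set is conspecific; a single tied heterospecific hit fails
the taxon. The query itself is excluded from the reference exactly when
its species has two or more sequenced individuals; a singleton species
therefore retains its perfect self-hit and succeeds vacuously in the
n >= 1 cohort. Whether such vacuous successes should be counted is a
reporting decision, not part of the criterion, so `similaritySuccess()`
exposes it as the `vacuousSingletons` switch (default on). At genus
level any congeneric hit (conspecific included) counts as success.

The scoring kernel is compiled (Rcpp) and, by default, restricts the
dynamic programme to a diagonal band of half-width 64 (automatically
widened by the length difference of the pair). For the near-homologous
sequences a barcode reference contains, the optimal local alignment lies
well inside this band -- BLAST itself relies on far more aggressive
heuristics -- and `band = 0` recovers the exact full alignment; the two
are held in agreement by tests on random homologous pairs.

## Cohorts and rates

`discriminationRate()` is successes/total over the evaluated taxa.
`evaluateDataset()` computes both criteria at both taxonomic levels for a
list of marker sets (by default each single locus and the cumulative
combinations in dataset order) and both cohorts: `n1` (all taxa with at
least one sequenced individual for the marker set) and `n2` (at least
two). All exclusions -- taxa with no sequence for a marker set, singleton
species in tree analyses -- are written to a structured log, never
silently dropped, because cohort denominators are part of the result.
Percentages are rounded half-up to one decimal (`computeRate()`), the
convention of printed recovery tables (381/412 prints as 92.5); R's own
half-to-even `round()` would disagree on exact halves.

## Supermatrix and simple indel coding

`concatenateLoci()` stacks per-locus alignments over the union of their
specimens, padding a specimen's missing loci with `?` and recording
0-based half-open partition intervals; extraction inverts concatenation
exactly. `simpleIndelCoding()` re-implements the classic simple indel
coding of shared gaps: each distinct internal gap span (identical start
and end columns) becomes one binary character; a sequence scores 1 when it
bears exactly that gap, 0 when it has residues across the span, and `?`
when its own gap strictly contains or partially overlaps the span, or the
span lies in a terminal missing region. Terminal gaps model recovery
failure and ragged sequencing ends, not indel events, and are never
coded. The indel block is export-only (NEXUS standard-data block): it
feeds parsimony/Bayesian analyses outside this package and never enters
the NJ distances.

## The placement audit (misidentification screening)

`flagMisidentifications()` operationalizes the reciprocal-illumination
loop of barcoding surveys: examine the NJ trees of the core barcodes and
of the combined supermatrix plus the best-hit lists; when a specimen's
molecular placement contradicts its a priori label in at least `quorum`
(default 2) of the marker-set analyses, flag it for morphological
re-examination, with a proposed identity. Nothing is relabeled
automatically -- the output is an audit table (original determination,
proposed determination, supporting evidence), because the confirmation
step is herbarium work by definition.

Per marker set, the audit works on the bootstrap-annotated NJ tree:

* A species whose labeled individuals are supported-monophyletic
  exonerates all of them.
* Otherwise the species' **core** is the union of the largest supported
  clades wholly contained in the labeled set -- where the species
  "really is" on the tree. Core members are exonerated; so is any
  specimen whose top hits or smallest supported clade neighbourhood reach
  a core member. A specimen outside all of that is a violation, and the
  majority label of its neighbourhood (violators and labeled conspecifics
  excluded) is the proposed species.
* When no coherent core exists (the labeled species is scattered across
  the tree), a specimen is flagged only if its neighbourhood is
  label-unanimous for a single other species. Unanimity is judged after
  removing specimens already identified as violators: a mislabeled
  neighbour's label carries no information, and two specimens of one true
  species swapped to different wrong labels would otherwise shield each
  other indefinitely. This re-examination iterates to a fixpoint.

The majority-core construction is deliberately stricter than "nearest
neighbour has a different label". When a swap removes an individual from
species A, the individuals left behind in A often have the relabeled
intruder as their nearest neighbour (the intruder *is* their true
conspecific); a naive nearest-label rule flags them as collateral
damage. Requiring violation of the core -- and exonerating anything that
still reaches its species' core -- keeps precision at 1 in the
strong-gap regime while the unanimity rule preserves recall for paired
and colliding swaps. These properties are exercised by the acceptance
tests against the simulator's truth registry across many seeds.

## The simulator

`simulateDataset()` generates the data structure the analysis assumes: a
genus/species/individual hierarchy (genera as deep clades, species inside
them, individuals as a star within each species), per-locus sequence
evolution under a two-parameter substitution process (transition:
transversion ratio 2, uniform rates across sites), shared indels (1--5
column deletions applied to a random subset of a species' individuals, so
indel coding sees genuinely shared spans), per-locus missingness
(independent Bernoulli drop of each specimen-by-locus sequence), and
planted label swaps recorded in a truth registry.

Divergence parameters are expected **pairwise** divergences -- the scale
on which the barcode gap (largest intra-specific vs smallest
inter-specific distance) is defined: conspecific pairs differ by
`intraSpecies` expected substitutions/site, congeneric heterospecific
pairs by `interSpecies`, inter-generic pairs by
`interGenusMultiplier * interSpecies`. Branch depths are derived from
these (individual branch `intra/2`, species branch `(inter - intra)/2`,
genus branch `(mult - 1) * inter/2`).

Three presets define the study conditions used throughout the tests:

* `strong_gap` -- 8 genera x 5 species x 3 individuals (120 specimens),
  two 600-bp loci (rate multipliers 0.8 and 1.2), intra 0.002 vs inter
  0.05, no missingness. Intra-specific pairs differ by ~1--2
  substitutions, inter-specific pairs by ~30: the distance distributions
  are literally disjoint, bootstrap supports saturate, and every
  discrimination criterion should return 100%. This is the
  parameter-recovery limit: if any criterion fails here, the pipeline --
  not the data -- is wrong.
* `weak_gap` -- the same design with intra 0.01 vs inter 0.015. At 600 bp
  the Poisson noise on realized distances makes the intra- and
  inter-specific distributions overlap substantially, the regime where
  barcodes genuinely fail; discrimination drops well below 100% and must
  sit strictly below the strong-gap rate on paired seeds.
* `paper_like` -- a survey-sized design: 12 genera, 133 species, 409
  specimens with 22 singleton species and two-to-nine individuals
  otherwise (mean ~3.5), five loci with lengths (665, 746, 508, 450, 845),
  the familiar variability ordering rbcL < matK < trnH-psbA < ITS2 < ITS
  (rate multipliers 0.5, 1, 2, 2.5, 3) and per-locus missingness 0.075,
  0.075, 0.216, 0.447, 0.609 -- the unrecovered fractions a Lauraceae-
  scale survey reports. rbcL carries no indels (its real alignments are
  indel-free); the faster loci do.

What the simulator does *not* model, and what passing tests therefore do
not show: intraspecific genealogy (individuals are a star, so there is no
incomplete lineage sorting), site-rate heterogeneity, alignment error
(the generator emits correctly aligned columns), ITS paralogy/secondary-
structure artifacts, and any resemblance to real sequence content. The
strong-gap acceptance results are statements about the pipeline's
correctness in a regime where the right answer is unambiguous, not
predictions of discrimination rates for real floras; the weak-gap
ordering shows the criteria respond to gap erosion in the expected
direction.

## Numerical and design choices

* **Distance models**: K2P with pairwise deletion is the default (the
  barcoding convention); p-distance and JC69 are selectable. Saturated or
  non-overlapping pairs are undefined; the default policy imputes them
  with the maximum defined distance plus 1e-4 and records the pairs in an
  audit attribute, keeping NJ runnable on sparse supermatrices (a `fail`
  policy is available). The matrix engine is `ape::dist.dna`; the
  exported closed-form pair functions are cross-checked against it.
* **NJ**: `ape::nj` (Saitou--Nei), with negative estimated branch lengths
  clamped to zero afterwards; lengths play no role in any success
  criterion. Correctness is accepted against a brute-force least-squares
  topology oracle on random additive matrices.
* **Bootstrap**: one seed drives column resampling; supports are the
  rounded percentage of replicates containing each reference bipartition.
  1000 replicates by default; the simulation studies use 100, which is
  ample when supports saturate (the quantities tested are 100 vs <=50,
  not 83 vs 85).
* **Problem sizes in the tests**: the acceptance studies run 5 seeds of
  the 120-specimen strong-gap design (and 3 in the acceptance script),
  10 paired seeds for the gap ordering, and 50 (script: 30) survey-sized
  generations for the missingness calibration -- sizes chosen so the
  whole suite completes on a laptop in minutes while every check retains
  an unambiguous expected outcome.
* **Determinism**: every stochastic entry point takes a seed, restores
  the caller's RNG state on exit, and is bitwise reproducible.

## Limitations

The audit rule is tuned to the structure of label errors (a specimen's
sequence is genuine; its label is wrong). It will not detect
contamination that fabricates chimeric sequences, nor errors in species
with a single sequenced individual and no conspecific reference, which
are reported as "insufficient data" rather than guessed at. Rates from
the n >= 1 similarity cohort include vacuous singleton successes unless
switched off, and all rates are conditional on the sampling: a species
that never yielded a sequence for a marker set is absent from that
denominator (but present in the log).
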