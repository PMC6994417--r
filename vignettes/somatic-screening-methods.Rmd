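---
title: "Somatic variant screening in a T-cell lymphoma cohort: methods and design"
author: "SomaticScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic variant screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SomaticScreen)
```

## The analytical problem

Peripheral T-cell lymphoma not otherwise specified (PTCL-NOS) cohorts are
typically sequenced in two tiers: a whole-exome *discovery* panel on frozen
tissue and a deep *targeted* resequencing panel on the full cohort,
supported by matched saliva normals for a minority of patients, a panel of
unmatched normals (PoN), and reactive hyperplastic lymph nodes as tissue
controls. Because most tumors lack a matched normal, somatic status must be
inferred through a cascade of filters rather than direct subtraction. This
package implements those cascades with a complete per-variant audit trail,
the downstream descriptive statistics (mutation spectrum, per-megabase
burden, gene recurrence), consensus functional-consequence calling,
protein-stability classification, and mutation-stratified overall-survival
analysis — plus a seeded synthetic-cohort generator used to validate the
whole chain end to end.

## The two filtering cascades

Both cascades are pure conjunctions over per-variant gates. Every gate is
evaluated for every variant, so the `FilterTrace` is complete even when an
earlier gate already failed; the *rejecting gate* is the first failure in
cascade order. Because the verdict is a conjunction, gate order affects only
attribution, never the retained set — the order used here is
cheapest-first.

**Exome (discovery) cascade** — `wesDiscoveryFilter()`:

1. *depth*: site depth ≥ 10× in tumor, and in the matched normal where one
   exists; a site missing from the matched-normal evidence counts as depth
   0 (it cannot be adjudicated as covered).
2. *vaf*: paired, tumor VAF > 10% and normal VAF < 3%; unpaired, depth
   > 20× and VAF > 25%. These thresholds are deliberately **strict**
   inequalities, matching the wording of the protocol they implement.
3. *pon*: identity key absent from the panel of normals.
4. *germline_db*: dbSNP members and variants with nonzero 1000 Genomes
   frequency are removed, unless COSMIC-listed.
5. *cosmic*: only COSMIC-listed variants are retained. Note this makes the
   dbSNP exemption of gate 4 logically redundant; both are traced so the
   audit trail mirrors the protocol's description.
6. *rna*: for patients with RNA-seq, the variant must be observed in the
   RNA evidence with ≥ 2 reads (`rnaConcordant()`); patients without RNA
   pass through.
7. *context*: the 41-base flanking context (variant base ± 20 bp) must
   occur exactly once in the reference, counting forward-strand and
   reverse-complement exact matches (`contextIsUnique()`). This is an
   exact-match stand-in for BLAT-style multi-mapping detection of captured
   pseudogenes. An odd-length DNA string can never equal its own reverse
   complement, so the two strand counts never double-count a hit.

**Targeted cascade** — `targetedFilter()`: (1) caller quality; (2) VAF
≥ 10% and (3) ≥ 3 supporting reads (**inclusive**, again following the
protocol's wording — note the asymmetry with the exome cascade is
intentional and literal); (4) 1000 Genomes frequency ≤ 1%; (5) COSMIC
membership; (6) dbSNP exemption (traced, subsumed by 5); (7) effect —
synonymous variants and intronic variants > 2 bp from the coding sequence
are excluded; (8) subtraction of any key present in the matched-saliva or
hyperplastic-control panel.

Thresholds are all named arguments of `filterThresholds()`, so a
sensitivity analysis is a one-argument change.

Two prose-level ambiguities were resolved as follows and are configurable:
"present in a normal" requires **≥ 2 supporting reads** (one read is
indistinguishable from sequencing noise at these depths), and RNA
"correspondence" likewise requires **≥ 2 RNA reads**. The published
protocol also included manual IGV curation of candidate calls; that step
has no computational counterpart here, which is a sensitivity caveat when
applying the cascades to real data.

## Functional consequence

`damagingVote()` implements the 4-of-9 consensus over the structure- and
homology-based predictors (PolyPhen-2, PolyPhen-2 HVAR/HDIV, LRT,
MutationTaster, FATHMM, RadialSVM, LR, MutationAssessor), whose calls are
*inputs* — the package never recomputes a predictor. A missing output
counts against the vote (conservative; the alternative of ignoring missing
slots would let a 1-of-1 vote pass). The vote applies to **missense**
variants only: structure/homology predictors score amino-acid
substitutions, so protein-truncating and splice-site classes (stop-gain,
frameshift, splicing) pass the consequence step by class. This choice is
also forced by internal consistency of the published gene-level counts,
where several genes report more mutated samples than scored missense
variants (e.g. 11 mutated samples versus 9 scored missense variants in
ATM). The vote sits *after* filtering and *before* recurrence counting.

`classifyStability()` labels a missense variant destabilizing when its
predicted folding free-energy change is below −0.5 kcal/mol — strictly, so
a variant at exactly −0.5 is non-destabilizing; `destabilizingFraction()`
reports `k/n` over a gene's scored missense set.

## Cohort statistics

`spectrumSummary()` counts transitions (A↔G, C↔T) and transversions,
reports the Ti/Tv ratio both at full precision and truncated to one
decimal (the conventional rendering: 1676/857 = 1.9557 prints as 1.9), the
six pyrimidine-collapsed substitution classes, and the fraction of SNVs
with G/C reference base. `mutationBurden()` divides per-sample
nonsynonymous counts by the effective exome size; the default of 54 Mb is
the value consistent with a median of 135 mutations per patient at 2.5
mutations/Mb. `recurrenceMatrix()` collapses to one hit per gene per
sample before counting, so row sums are mutated-*sample* counts.
`buildPanel()` enforces that literature genes added to a targeted panel be
disjoint from the exome-derived set. `hScore()` is the
immunohistochemistry positivity × intensity product on [0, 300].

## Survival analysis

`kmEstimate()` is a native product-limit implementation: censored
observations tied with an event time are counted at risk at that time
(events before censorings). `kmMedian()` returns the smallest time with
S(t) ≤ 0.5; when the curve sits exactly at 0.5 over a plateau the plateau
*start* is returned. This matters because the synthetic clinical fixture
plants an uncensored event exactly at the median-defining rank; note that
`survival::survfit` reports the plateau midpoint in that situation, which
is why the cross-check tests compare curves point-wise rather than through
the median. `logrankTest()` is the Mantel–Cox form — per-event-time
hypergeometric expectations with the summed-variance statistic, not the
pooled (O−E)²/E approximation — and agrees with `survival::survdiff` to
numerical precision on random fixtures. `stratifyByGene()` partitions a
clinical table by retained nonsynonymous mutation status of one gene.

## The synthetic cohort generator

`generateCohort()` emulates the published cohort structure from a
`CohortProfile`: 21 discovery + 50 extension tumors (4 + 8 with matched
saliva), 20 PoN saliva normals, 8 hyperplastic controls, 18 RNA-sequenced
discovery tumors; a 137-gene panel (92 exome + 45 literature genes);
per-gene mutated-tumor counts (FAT1 28/71, KMT2C 23/71, …, filled so that
exactly 52 genes reach ≥ 2 mutated tumors); a discovery burden list with
median 135 and range 6–204 (individual per-patient counts are not
published, so the list is synthetic subject to those order statistics); a
Ti/Tv ratio of 1676/857 with a G/C reference-base bias of 0.6 (the
published spectrum reports preferential G/C targeting qualitatively; 0.6
is a realistic modest bias chosen once).

Three truth classes are planted on a toy reference (~920 kb, one
chromosome, 2 kb gene intervals):

* **somatic** variants survive both cascades *by construction*: depth
  40–200× (exome) or 300–1500× (targeted), VAF 0.30–0.60, ≥ 3 supporting
  reads, COSMIC members, zero population frequency, absent from every
  normal, unique flanking context, nonsynonymous effect, and — for
  missense — a ≥ 4-of-9 damaging vote. Five tumor-suppressor genes carry
  fixed missense/ΔΔG structures reproducing the published destabilizing
  fractions (LATS1 2/3, STK3 3/4, TP53 2/3, TP63 3/5, ATM 5/9; FAT1 > ½).
* **germline** contaminants (default 50 per tumor from a 300-key pool) are
  dbSNP members with 1000 Genomes frequency 0.02–0.40, present at ~50% VAF
  in the tumor, its matched saliva, and scattered PoN/control normals.
* **artifacts** (default 20 per tumor from a 100-key pool) appear with low
  support (≥ 2 reads) in 1–3 PoN normals and 1–2 hyperplastic controls; a
  configurable subset sits inside duplicated-context blocks of the toy
  reference, mimicking COSMIC-listed pseudogene calls that only the
  context gate can expose.

The defaults are deliberately large enough that a broken gate is caught by
the full-recovery property test (100% sensitivity on planted somatic, zero
contaminant survivors) rather than slipping through by chance. Everything
is drawn from a single seeded stream, so one `(profile, seed)` pair yields
a byte-identical bundle.

What the generator does **not** emulate: read-level errors, trinucleotide
signature structure, copy-number events, tumor purity gradients, FFPE
artifact spectra, or caller-specific quirks. A green recovery suite
demonstrates the cascades implement their specification — not that the
thresholds are optimal for any particular real data set.

### Exact survival landmarks

The clinical layer plants its Kaplan–Meier landmarks exactly rather than in
expectation. Group medians are straightforward: with an even at-risk count
r, placing r/2 uncensored deaths so the last falls exactly at the target
median makes S(median) = 0.5 at the plateau start. The fixed-time landmark
is subtler: a 36-month survival of 0.24 is *not* expressible as k/61, so no
censoring-free construction at n = 61 can achieve it. The generator
therefore censors a computed number of patients at the follow-up minimum —
before the first event — bringing the at-risk set to the largest r ≤ n with
r × S(36) integral (r = 50 at n = 61), and places only deaths between that
point and month 36, making S(36) = (r − deaths)/r exact. All times stay
inside the profiled follow-up range, and jointly infeasible specifications
raise an error rather than silently approximating. Because all landmarks
hold by construction, they are invariant to the seed; the seed only
permutes which patient receives which time.

## Problem sizes and runtime

The reference bundle holds ~3,200 distinct planted variant keys and
~12,000 variant-table rows; generation takes a few seconds and each
cascade pass under half a minute on one core, which keeps the full test
suite and the acceptance script in the low minutes. The down-scaled test
profile (10 tumors, 7 panel genes) exercises every code path in under
three seconds.

## Known limitations

* The cascades consume *called* variants; alignment, calling and quality
  recalibration are upstream and out of scope, as is annotation
  computation (population frequencies, predictor calls and ΔΔG values are
  inputs).
* Context uniqueness is exact-match only; real BLAT tolerates mismatches,
  so the stand-in is stricter than the original procedure.
* The log-rank comparison is two-group and unadjusted (as in the study it
  follows); no proportional-hazards modelling is provided.
* Indel normalisation trims shared affixes without reference-based left
  alignment across repeat tracts; the generator emits SNVs only.
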