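---
title: "Reanalysis of unsolved clinical exomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reanalysis of unsolved clinical exomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomerescue)
```

## The problem

Roughly a quarter to a third of patients referred for clinical exome
sequencing receive a molecular diagnosis on the first, usually proband-only,
pass. The remainder are not necessarily unsolvable: adding parental exomes,
re-examining variants under every Mendelian inheritance model, and looking
for signals that routine pipelines discard — low-fraction parental mosaics,
whole-chromosome absence of heterozygosity, single-exon deletions hidden in
coverage data — recovers diagnoses at a substantial rate. `exomerescue`
implements that reanalysis workflow as a set of small, testable components,
together with a synthetic cohort generator so that each component can be
exercised and scored without access to patient data.

## De novo detection: parental subtraction plus read-count criteria

A candidate de novo variant is a site called in the proband at which neither
parent carries the alternate allele (`subtract_parental()`). Genotype-level
subtraction is deliberately naive — it keeps every artifact of uneven
coverage — so it is followed by four allelic-depth criteria
(`dnm_criteria()`), all strict inequalities:

1. proband alternate reads > 5;
2. proband alternate/reference read ratio > 30%;
3. reference reads > 10 in **each** parent;
4. alternate/reference read ratio < 5% in **each** parent.

Criteria 1–2 require convincing support in the child; criteria 3–4 require
convincing evidence of *absence* in the parents — a parent with shallow
coverage cannot demonstrate absence, which is why poorly covered regions are
parsed out rather than called. Zero-denominator conventions are ours, since
convention must be chosen somewhere: a proband with zero reference reads has
an infinite alt/ref ratio and passes criterion 2; a parent with zero
reference reads fails criterion 3 and leaves criterion 4 indeterminate
(never counted as a pass). Sites where a parent's genotype is missing are
excluded from de novo calling and counted, because subtraction requires
evidence of absence, not absence of evidence.

## The stepwise inheritance workflow

`run_stepwise()` applies four analysis steps after a population-frequency
filter (retain MAF < 0.5%, strict; variants with *no* MAF annotation are
novel and always retained — "absent" is deliberately not collapsed to zero
so that reporting can distinguish the two):

1. **AR-homozygous** (plus X-linked hemizygous in male probands):
   loss-of-function (stop-gain, frameshift, splice-site) and/or missense
   variants homozygous in the proband with both parents heterozygous.
   A proband homozygote whose parents cannot both have transmitted it is
   *not* discarded: it is classed `mendelian_inconsistent` and is exactly
   the signature that the UPD and deletion detectors explain.
2. **Compound heterozygous**: pairs of rare LOF/missense hets in one gene,
   one transmitted by each parent (trans). Pairs involving a variant carried
   by both parents are phase-undecidable and reported `phase_unknown` rather
   than guessed; single-parent (cis) pairs are excluded. In proband-only
   mode all het pairs per gene are reported `phase_unknown`.
3. **Heterozygous LOF**: LOF-only by its purpose — it is what surfaces
   truncating de novo events in proband-only cases.
4. **De novo + parental mosaicism screen** (trio mode).

All steps always run; the workflow never stops at the first hit, because
dual molecular diagnoses — two independent genotypes blending into one
phenotype — are a documented failure mode of first-hit analysis. Missense
variants participate in steps 1–2 only. Pathogenicity predictions are
consumed as optional annotations for sorting, never as hard filters, because
no principled threshold is available.

## Parental mosaicism

A constitutional heterozygote is expected to show ~50% variant reads. The
mosaicism screen computes each carrier's exact variant-read fraction and an
exact two-sided binomial p-value against 0.5 (`binomial_deviation_test()`,
minimum-likelihood two-sided definition, computed by direct enumeration of
the pmf). A parent is flagged (`flag_parental_mosaic()`) when it deviates at
`alpha = 0.01` while **every** carrier child is consistent with
constitutional heterozygosity — the asymmetry between generations is the
mosaic signature. Defaults: `min_total_reads = 20` below which the verdict
is `insufficient_depth`; at least one affected carrier child.

Two caveats worth stating. First, published analyses of this design report
p-values for the motivating read counts (for example 6/38 against 0.003)
that no standard exact binomial against 0.5 reproduces (6/38 gives
~2.4e-5); the test actually used is not stated. We implement the exact
binomial and treat only the read counts, never those printed p-values, as
checkable quantities. Second, `alpha = 0.01` was chosen to sit conservatively
inside the interval that separates the clearly-deviating parental fraction
from the children's fractions in that motivating family; it is exposed in
`mosaic_config()`.

## B-allele frequency, AOH, and uniparental disomy

`compute_baf()` is the exact per-site alternate read fraction, with a
depth gate (`min_total_reads = 15`) marking unreliable markers
non-informative. `detect_aoh()` is a maximal-run scan: consecutive
informative markers whose BAF falls outside the heterozygous band
(default [0.15, 0.85]) form a segment if the run has at least 50 markers.
Run-length scanning was chosen over windowed heterozygosity rates because
the signal of interest — isodisomic UPD — is chromosome-scale and
essentially noise-free at exome depths; every parameter is exposed in
`aoh_params()`.

`flag_upd()` flags an autosome when its AOH segments cover ≥ 80% of its
informative markers ("almost the entire chromosome" is not quantified in
the motivating description; 0.80 is our operating point) *and* AOH across
the remaining autosomes stays ≤ 10% — the single-region condition.
Multiple chromosomes above threshold indicate consanguinity, not UPD, and
are reported as such without flagging. chrX is excluded: male hemizygosity
mimics chromosome-wide AOH. `infer_upd_parent()` then counts
Mendelian-inconsistent homozygous sites attributable to each parent and
requires a ≥ 90% majority. Heterodisomy (UPD without AOH) is invisible to
this method and documented as out of reach.

## Coverage-dropout deletions

Raw exon read counts are normalized per sample — length rate divided by the
sample's median rate (`normalize_exon_coverage()`), making the measure
invariant to library size. `call_dropout_deletions()` then finds, per
sample and gene, maximal contiguous exon runs where the sample's normalized
coverage is ≤ 10% of the cohort median, restricted to exons whose cohort
median is itself ≥ 0.30 (an exon badly covered in everyone cannot witness a
deletion; such exons also break runs, so calls never span them). The default
`min_exons = 1` is the point of the method — single-exon "dropout alleles"
are precisely what multi-exon CNV callers requiring three contiguous exons
miss, and setting `min_exons = 3` reproduces that blind spot (asserted as a
regression test). Near-zero residual coverage implies loss of both copies,
so calls are homozygous, or hemizygous for chrX genes in males.
Heterozygous-dosage calling is out of scope: it needs a calibrated diploid
baseline this design does not provide. Thresholds here are our design
choices, exposed in `deletion_params()`.

## Cohort-wide stop-gain scan and reporting

`tally_rare_homozygous_stopgain()` ranks genes by the number of *distinct
individuals* carrying a rare (< 0.5%) homozygous (or male-hemizygous)
stop-gain — carrier count rather than variant count, since recurrence
across individuals is the discovery signal; the variant count is reported
alongside. `summarize_yield()` turns a family-outcome table into category
counts and rates by family structure and phenotype group;
`project_overall_yield()` combines a first-pass clinical rate with the
residual research rate as `initial + (1 - initial) x residual`. Percentages
round half away from zero via `format_rate()`. The bundled
`pilot_outcomes()` table encodes the published marginal counts of a
74-family pilot cohort; joint cells not determined by those marginals are
filled deterministically and only marginal rates are meaningful.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the detectors
assume, not sequencing itself (no reads, no mapping artifacts, no indel
realignment noise):

* a shared site grid (default 20,000 sites; ~4% on chrX, the remainder
  split over the autosomes; evenly spaced positions; gene blocks of 10
  sites) with population MAF annotations drawn from a mixture of common
  point masses (0.10/0.25/0.40) and a uniform rare tail on [0, 0.05].
  Genotypes are sampled at the annotated frequency under Hardy–Weinberg,
  children inherit one allele per parent, chrX is hemizygous in males, and
  pseudoautosomal regions are not simulated;
* allelic depths: Poisson total (mean 40, matching research-reanalysis
  exomes rather than 130x clinical ones; no published variance model
  exists, so Poisson is the parsimonious choice), binomial alternate split
  at the genotype's allele fraction perturbed by a base error of 0.005;
* planted events for every detector (de novo, AR-homozygous, compound het
  in trans, X-linked hemizygous, parental mosaic at a configurable
  fraction, whole-chromosome isodisomy with a guaranteed
  Mendelian-inconsistency witness site, exon dropout), each recorded in a
  truth table.

Planted variant sites are generated *clean*: exact genotype fractions, no
base-error perturbation, zero alternate reads in non-carriers. A planted
event thus models a validated true positive, and recovery sensitivities of
1.0 are meaningful contracts rather than statements about error
robustness — which is exercised separately, by the error model on the
20,000 background sites and by the Monte-Carlo mosaicism replicates. As an
extension, a de novo event accepts `proband_fraction` below 0.5 to emulate
low-fraction artifact-like calls that survive subtraction but fail the
read-count criteria, which is how the subtraction-vs-criteria reduction
property is tested.

What passing tests on this generator do **not** show: robustness to
alignment artifacts, batch effects in capture efficiency, segmental
(partial-chromosome) UPD, heterodisomy, multi-nucleotide error modes, or
real population allele-frequency spectra. The generator's role is to verify
the decision logic at the published operating points, not to certify
performance on real exomes.

## Numerical and design notes

* All rate thresholds follow their verbal definitions strictly
  ("greater than 5" excludes 5); the de novo module uses alt/ref ratios as
  written, while the mosaicism module uses alt/total — both conventions are
  kept deliberately and tested.
* Dinucleotide substitutions emitted as two adjacent SNV records with
  identical genotype classes across all samples are merged
  (`merge_adjacent_snvs()`); merged depths are the per-sample elementwise
  minimum (conservative support). The merge is greedy left-to-right and
  idempotent.
* Determinism: a mandatory simulator seed; identical configs give
  byte-identical VCF/PED/TSV outputs; candidate tables sort on
  (step, chromosome, position, sample) so reports are reproducible under
  input shuffling.
* Problem sizes used by the test-suite and the acceptance script — a
  10-trio cohort on a 20,000-site grid at depth 40, 500 mosaicism
  replicates, the exhaustive 16^6 read-depth decision grid — were chosen as
  the smallest sizes at which every detector's operating regime
  (≥ 200 markers per chromosome for AOH, ≥ 50-marker segments, binomial
  tail behavior at exome depths) is genuinely exercised.
* The per-module command-line entry points one might expect from a
  pipeline tool are deliberately not shipped; the exported functions are
  the interface, and `write_candidates()` / `write_cohort()` provide the
  deterministic file outputs an orchestration layer needs.

## Known limitations

Upstream alignment and variant calling, consequence prediction,
knowledge-base prioritization (OMIM/ClinVar-style), ACMG classification,
mitochondrial DNA, and third-party CNV callers are all out of scope: the
package consumes annotated VCFs and coverage tables and stops at candidate
generation and reporting. Read counts come from the VCF `AD` field rather
than BAM pileups; `AD` carries the same statistic at desk scale. Phase is
always inferred from parents, never from read-backed phasing.
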