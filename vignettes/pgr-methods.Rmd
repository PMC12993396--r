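---
title: "Methods: phenotype-aware proactive reanalysis of clinical exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-aware proactive reanalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most children who undergo clinical exome or genome sequencing do not receive
a molecular diagnosis at first analysis, yet gene-disease knowledge, variant
classifications and the patients' own phenotypes keep evolving. Reanalysis
of stored data recovers diagnoses, but clinician-initiated reanalysis is
sporadic. `pgrpipe` implements an institution-style *proactive* reanalysis
pipeline: a deterministic filter cascade nominates candidate variants, a
neural network ranks them by integrating genotype, population, in-silico and
phenotype-match evidence, and codified review rules reduce the survivors to
a one-to-two-variant internal report per proband. Because institutional
cohorts cannot be redistributed, the package ships a seeded synthetic-cohort
generator with planted causal variants, so every stage runs against ground
truth.

## Pipeline stages and their parameters

**Cohort family analysis (CFA).** Candidates are variants carried by a
proband. A variant survives when all clauses hold (`cfa_thresholds()`):

* impact tier HIGH or MODERATE, or a ClinVar P/LP assertion, within 20 bp of
  an exon (`exon_flank_bp = 20`);
* allele frequency at most 1.5% in both the reference database and the
  internal cohort (`max_af = 0.015`); missing frequencies count as 0 —
  absence from a population database *is* the evidence of rarity, whereas
  missing in-silico scores never satisfy an evidence requirement;
* heterozygous carrier count at most 30 and homozygous count at most 2,
  summed over the loaded cohort's probands and the optional
  `ref_het_count`/`ref_hom_count` reference columns (the source cohort for
  these counts is genuinely ambiguous in practice, so both are summed and
  the columns are optional);
* no benign evidence: ClinVar benign/likely benign or an automated ACMG
  class of B/LB rejects;
* genotype quality: depth ≥ 10 and GQ ≥ 20;
* an interpretable inheritance pattern in trios (de novo, homozygous,
  hemizygous, compound het, segregating with an affected parent, or
  inherited-but-unphased; only pattern `unknown`, e.g. from a missing
  parental genotype, rejects);
* in duos and singletons, where de novo status cannot be established, a
  stricter branch: frequency at most 0.1%, strong in-silico or constraint
  evidence (CADD ≥ 25, pLI ≥ 0.9, s_het ≥ 0.05 or SpliceAI ≥ 0.5), and
  either patient-gene phenotype overlap (at least one exact or one-level
  HPO match) or a ClinVar P/LP assertion.

Compound hets are paired in trios only when parental origins differ; in
non-trio families, pairs of rare hets are provisionally flagged, and only in
genes with a recessive mode, because an unphased pair in a dominant gene has
no interpretation that the reviewer rules could accept.

**Inheritance conventions.** Any non-pseudoautosomal chrX alt call in a male
is hemizygous; the PAR table is configurable and empty for the synthetic
genome, which has no PAR. Multi-allelic sites are split into biallelic
records before filtering because every threshold is per-allele.

**Phenotype model.** The ontology is a DAG loaded from OBO; term level is
minimum depth with the root at level 1. Information content is the
Resnik-style corpus measure \(IC(t) = -\ln(n_t/N)\) over ancestor-propagated
gene annotations, on a natural-log scale; the match-specificity cutoffs 2
and 4 therefore correspond to terms annotated to fewer than \(N e^{-2}\)
and \(N e^{-4}\) genes. Both the log base and the cutoffs are arguments.
Terms never annotated receive an infinite IC sentinel and are excluded from
most-informative-common-ancestor (MICA) searches. Match features count
exact term intersections, matches one ontology level apart (a direct parent
or child of a patient term, each patient term contributing at most once;
siblings are excluded by default, with an `include_siblings` flag), and
exact matches above each IC cutoff — the cutoffs are applied to exact
matches only. The built-in similarity is the symmetric best-match-average
Resnik score; when external phenotype scorers are absent their feature
slots fall back to this similarity. Combined profiles are the union of
manual and NLP terms minus obsolete terms, with no ancestor-redundancy
collapsing — the downstream features consume counts, and annotation
granularity is itself informative.

Note one property deliberately *not* asserted: best-match-average
self-similarity dominance holds for singleton term sets but not in general
(a cross-set direction mean can exceed the self mean when a set mixes low-
and high-IC terms), so the test suite asserts it only where it provably
holds.

**Feature encoding.** The scorer consumes an ordered 43-slot vector:
17 numeric slots (allele fraction, depth, reference and cohort frequency,
three phenotype-scorer slots, HPO match count, IC-2 and IC-4 match counts,
CADD PHRED, REVEL, AlphaMissense, SpliceAI, MisFit-D, s_het, pLI) and
one-hot expansions of the inheritance call (6 levels; `unknown` is the
all-zero reference), gene mode of inheritance (4, multi-hot over AD/AR/
XLD/XLR), impact tier (4), ClinVar class (7) and automated ACMG class (5).
The 21 input families do not map one-to-one onto 43 numeric slots, so two
constraint scores (s_coef, MisFit-S) are represented by their close
correlates (s_het, MisFit-D) rather than given slots; the schema is a data
frame and fully replaceable. Missing numerics are median-imputed with the
medians fitted on training rows; the missingness mask is recorded but is
not itself a feature (that would change the 43-slot contract).

**The scorer.** A feed-forward network with two rectifier hidden layers
(64, 16), a logistic output, class-weighted cross-entropy (weight =
negative:positive ratio by default, countering the roughly 13:1 imbalance
of the synthetic training sets), full-batch Adam (learning rate 0.01, up to
200 epochs) and seeded initialization — full-batch training makes runs
bit-reproducible under a fixed seed. When a validation set is supplied the
epoch with the lowest validation loss is kept (patience 25). 30% of the
dataset is reserved for validation, stratified by strongest label and
grouped by proband so no proband straddles the split; after evaluation the
production model is retrained on the full dataset. The decision threshold
is 0.5 and is inclusive: a score of exactly 0.5 is flagged. Evaluation
follows report-based definitions — true positives are reported variants
scoring at or above threshold, false negatives reported variants below it,
false positives unreported variants at or above it — with per-class metrics
obtained by restricting positives to P/LP or VUS against the shared
false-positive set, and AUC as the midrank Mann-Whitney statistic.

**First-pass review.** Ordered clauses, first failure wins:
(1) in-silico consensus benign (majority of available scores below
CADD 10 / REVEL 0.2 / AlphaMissense 0.34 / SpliceAI 0.1 — the consensus
rule is a package default, exposed in `review_config()`);
(2) population frequency at the locus, summing allele counts and
frequencies over co-located alleles of the same impact tier: recessive
calls require summed AF ≤ 0.001, hom/hemi ≤ 2 and any hom/hemi presence
needs a strong phenotype match; dominant calls outside NDD genes require
summed AC ≤ 2 unless incomplete penetrance or a compelling match; dominant
calls in NDD genes are checked against control (AC ≤ 2) and non-neuro
(AC ≤ 1) populations; hom/hemi presence is never allowed for dominant
calls; (3) inheritance-call versus gene mode-of-inheritance consistency;
(4) susceptibility-only gene associations are never returned;
(5) a phenotype-similarity floor (default 0.5); (6) an automated
read-support proxy replacing interactive alignment review: het allele
fraction in [0.25, 0.75], hom/hemi ≥ 0.85, depth ≥ 10. The
"strong/compelling match" threshold defaults to the 90th percentile of the
scored candidates' similarity distribution, resolved at pipeline run time.

**Second pass.** The codified ACMG subset (PVS1, PS2, PM2, PM3, PP3, BP4,
BA1, BS1, BS2) is combined under the Bayesian points framework: evidence
strengths are exponents of the base odds 350 (supporting 1/8, moderate 1/4,
strong 1/2, very strong 1; benign evidence subtracts), the prior is 0.10,
and the posterior bins are P (> 0.99), LP (0.90, 0.99], VUS [0.10, 0.90),
LB [0.001, 0.10), B (< 0.001) — the VUS bin is closed at 0.10 so that an
empty criteria set (posterior = prior) is a VUS. BA1 is stand-alone benign.
A candidate is returnable when P/LP or a VUS leaning P/LP (posterior >
0.5). The second pass also rejects candidates already documented for the
proband and applies a stricter similarity floor (default 1.0). All numeric
constants of the combiner come from the published framework, not from any
cohort, and are arguments.

**Branch pruning experiment.** To emulate phenotype clusters that were not
yet recorded at first analysis, each proband's manually curated terms are
partitioned by third-level ancestor (multi-parent terms join every level-3
branch they reach, so removing a branch removes the entire cluster; terms
above level 3 form a residual branch). Removing one branch at a time, the
phenotype features are rebuilt and the proband's variants re-scored; deltas
are compared between true-positive and false-negative validation variants
with two-sided Wilcoxon rank-sum tests, Benjamini-Hochberg adjusted. The
rank-sum test enumerates the exact null (with midranks, so ties are exact)
up to a pooled size of 12 and uses the tie-corrected, continuity-corrected
normal approximation beyond.

## The synthetic cohort

The generator emulates the study conditions at desk scale: 300 families
(half trios, a quarter duos, a quarter singletons), a 60-gene panel with an
AD/AR/XLR mix of 0.5/0.35/0.15, and causal variants planted in 60% of
probands — de novo in trios, homozygous or truly phased compound-het for
recessive genes, maternally inherited hemizygous males for X-linked genes
(resampled if the family has no male proband). Half of the planted variants
carry deliberately weaker, VUS-like in-silico support, mirroring the
roughly half-VUS composition of real reported-variant training sets. Each
proband receives ~52 background variants whose frequency, carrier-count,
impact, region and quality spectrum deliberately straddles every filter
threshold, so each rejection reason is exercised by construction; a small
set of "decoy" variants match the patient phenotype but each violate
exactly one review rule. Gene disease annotations are drawn within a single
level-3 ontology branch so that pruning that branch removes the gene's
phenotype signal completely. NLP term sets are the manual sets with 20%
dropout plus two spurious terms. About 5% of causal findings are marked as
already documented. The resulting training sets have roughly 13 negatives
per positive — the same order of imbalance as real reanalysis training
data. Planted causal variants have zero reference-database frequency and
zero internal cohort frequency (a novel finding is absent from *prior*
cohorts by definition).

What the generator does **not** emulate: linkage and population structure,
multi-gene or incomplete-penetrance phenotypes, annotation errors,
sequencing batch effects, related families, real genome coordinates or
read-level evidence. Passing tests therefore demonstrate that the
machinery implements its stated rules and recovers signal planted under
those rules — not clinical performance on institutional data, whose
headline metrics are not reproducible without the undeposited cohort.

## Problem sizes used by the tests

Unit and property tests run on 40-family cohorts and hand-built fixture
ontologies; the end-to-end suite and the acceptance script use the default
300-family cohort (about 16,000 candidate variants, 2,700 training rows),
chosen so the full build — generation, filtering, training, review and the
pruning experiment — completes in a few minutes on one core. Oracles are
independent reimplementations: a per-row if-chain reference filter for the
CFA, brute-force ancestor walks for information content and branch
partitions, closed-form evaluation for the criteria combiner, full
enumeration for the rank-sum test, and an external ROC implementation for
the AUC statistic.

## Known limitations

* Recovery of planted variants by the full pipeline is measured on the
  cohort the final model was retrained on (the validation metrics, by
  contrast, are leakage-safe); this mirrors the operational setting, where
  the production model is applied prospectively, but it is not an unbiased
  generalization estimate.
* Negative training instances are drawn only from probands that have
  reported variants; probands without reports form the application set.
* The automated ACMG subset covers 9 of the 28 criteria — those computable
  from the data the pipeline carries; literature-dependent criteria are out
  of scope.
* The in-silico consensus rule (which scores, which cutoffs, how many must
  agree) is a package default, as is the exact one-hot expansion of the
  43-feature schema; both are configurable inputs rather than claims about
  the original system.
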