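---
title: "Methods: rare-CNV burden and ENS candidate-gene prioritization"
author: "hscrcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-CNV burden and ENS candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscrcnv)
```

This vignette documents the statistical models, the parameter choices and
the design decisions behind the package, in the order the pipeline runs.

## Cohort structure

The pipeline analyses four groups: patients with Hirschsprung disease (HSCR)
and additional anatomical malformations but no known causal coding variant
(group 1), patients with a known pathogenic coding variant (group 2),
isolated HSCR without a causal variant (group 3), and unaffected controls
(group 4). The synthetic generator defaults to 23 / 15 / 20 cases and 326
controls. Where sources disagree on the group-3 size (20 vs 30), the
generator follows the arithmetic that makes the three case groups sum to 58;
group sizes are plain configuration fields either way and nothing downstream
hard-codes them.

## Rarity classification

Coordinates are stored 0-based half-open (BED convention). Tabular patient
coordinates written 1-based inclusive (e.g. `chr2:40,624,267–40,646,501`)
are converted on input via the `onebased` dialect; that example spans
22,235 bp.

A control individual *matches* a case CNV when the union of that
individual's calls of the same state class covers at least `min_overlap`
(default 0.75) of the case call. Three choices deserve justification:

* **State pooling.** Heterozygous, homozygous and hemizygous losses pool
  into one "loss" class for matching; gains match gains only. A patient
  deletion that is fully covered by control deletions of any zygosity is
  not novel dosage loss.
* **One-way overlap.** The covered fraction of the *query* is used, not a
  reciprocal criterion — the conservative reading when only "overlap of at
  least 75%" is specified. `reciprocal = TRUE` adds the symmetric
  requirement (the case call must also cover 75% of the union of the
  matching individual's overlapping calls).
* **Individuals, not calls.** The frequency denominator is the control
  cohort size (19,584 in the emulated study) and matches are counted per
  control sample: rarity is about how many *people* carry the variant.
  Tiled or fragmented control calls are unioned first so they are not
  double-counted.

The default frequency cutoff is 0.00026 (0.026%, chosen in the emulated
study to sit at HSCR prevalence). "Absent from controls" is the special
case `freq_cutoff <= 1/control_n`; with a 326-sample control cohort any
single carrier already exceeds 0.026%, so the two readings coincide there.
Rarity is monotone by construction: adding control calls can only raise the
carrier count.

Size z-scores standardize call sizes over the rare-call reference set with
the sample (n−1) standard deviation, optionally within state class, so
group size profiles can be compared on a common scale.

## Gene content and the CCR rule

A gene is *impacted* by a CNV at ≥ 1 bp overlap (half-open, so abutting
intervals do not touch). No minimum fraction is imposed: a deletion clipping
any part of a locus can disrupt it.

A gene is a constrained coding region (CCR) when

> (pLI ≥ 0.85) **or** (missense z ≥ 3) **or** (synonymous z ≥ 3) **or**
> (deletion score ≥ 1 **and** duplication score ≥ 1 **and** CNV score ≥ 1),

**and** it is not recurrently impacted by deletions or duplications in
unaffected controls (each event count ≤ 1). The sequence/dosage clauses are
combined with OR: several published candidate genes (e.g. one with a CNV
score of −2.53) fail the dosage clause outright yet are constrained by pLI
alone, so an AND reading would contradict the gene list the rule is meant to
produce. All thresholds are exposed as arguments. Missing metrics make a
clause false rather than propagating NA; a gene with no metrics at all is
*undetermined*, which is reported as not-CCR but kept distinct from an
evaluated negative in the prioritization report.

Whether "impacted more than once" counts events in external control
databases or within the study cohort is not specified in the source; the
implementation takes per-gene control event counts as an input column with a
threshold, which supports either interpretation.

## ENS-gene calling

The expression input is a genes × samples log2 matrix over three classes:
ENS cells isolated with GDNF, ENS cells without GDNF, and whole intestine /
other intestinal cells. The protocol is:

1. **Quantile normalization** of the complete matrix (ties receive the mean
   of their tied ranks' targets; missing values stay missing). This runs
   *before* gene filtering: normalization assumes the bulk of genes is
   unchanged, and on data where the filter would retain mostly
   differentially expressed genes, normalizing the filtered matrix would
   flatten the very signal being tested. Normalizing at import is also the
   order of the array protocol the pipeline emulates.
2. **Filtering**: a gene is kept when at least 20% of its non-missing
   values lie ≥ 1.5-fold from the gene median and less than 50% of samples
   are missing. Replicate rows sharing a gene id are averaged beforehand.
3. **Random variance model.** Per-gene precisions are modelled as
   1/σ² ~ Gamma(a, b) (shape–scale), so residual variances satisfy
   s²·a·b ~ F(m, 2a). `(a, b)` are fitted once on the pooled filtered
   matrix by maximizing the F likelihood (Nelder–Mead on log-parameters,
   relative tolerance 1e-10, moment-based start using the inverse-trigamma;
   non-convergence and all-equal variances are errors). The moderated
   two-sample t uses the shrunken variance s̃² = (m·s² + 2/b)/(m + 2a) on
   m + 2a degrees of freedom; as a → 0 and 1/b → 0 it reduces to the
   classical pooled t, which the tests verify on every input shape.
4. **Permutation p-values**: class labels are permuted identically across
   genes; p = (1 + #{|t*| ≥ |t|}) / (B + 1) with B = 1000, so p is never
   zero — necessary because the nominal 0.05 level is applied directly to
   these p-values. When the two classes admit at most B distinct label
   assignments the implementation enumerates all of them and reports the
   exact fraction instead. Label-wise (not gene-wise) permutation is the
   standard class-comparison scheme and is what is implemented.
5. **The call**: a gene is an "ENS gene" when, in **both** contrasts
   (ENS+GDNF vs comparator and ENS−GDNF vs comparator), the fold change is
   ≥ 1.5 in the ENS direction and the permutation p < 0.05. The "both"
   requirement is the strict reading of "with and without GDNF";
   `rule = "any"` preserves the alternative. Which comparator class the
   original series used is not fully specified, so the comparator label is
   a parameter (default `intestine`).

No multiple-testing correction is applied — the emulated protocol states a
nominal univariate 0.05 — so the per-gene false-positive rate is controlled
only by the two-contrast conjunction (≈ α² under independence). This is
deliberate and should be kept in mind when interpreting single-gene calls.

Missing values are handled complete-case per gene within each class; genes
with fewer than two complete values in either class are skipped and
reported as NA.

## Non-coding risk score

RSnc = Σᵢ ln(ORᵢ) · countᵢ over the risk-haplotype SNPs (defaults name the
six markers near *RET*, *NRG1* and *SEMA3C/D*). Odds ratios are required
input — the package invents no effect sizes; the synthetic model ships
literature-scale values (1.4–3.9) as its own defaults. Haplotype-combination
interaction bonuses are deliberately not modelled. Missing genotypes
contribute 0 by default; `impute_2pq_mean` substitutes the Hardy–Weinberg
expected count 2q (requiring an allele-frequency column), and `fail` makes
missingness an error. An OR of 1 contributes exactly zero, and the score is
additive over SNP subsets — both are tested to 1e-12.

## Group and zebrafish statistics

* Burden endpoints (CNV counts, summed sizes, ENS / CCR / ENS∧CCR gene
  counts, overall and losses-only) are compared with a one-way ANOVA;
  pairwise two-tailed pooled-variance t-tests run only when the ANOVA
  p < 0.05, mirroring the gated protocol. Welch tests are available by
  flag. Per-patient size dots are summed sizes by default (per-call values
  by flag) — the emulated figures do not state which was plotted.
* Zebrafish larvae are scored on the ordinal ENS scale I–V (I = fully
  colonized gut). The 2×2 comparison collapses categories to I vs II–V
  ("unaffected" vs any phenotype) and uses the "N-1" chi-squared:
  Pearson χ² × (N−1)/N on 1 df, the small-sample variant recommended for
  two-proportion tables. Zero margins are errors rather than silent zeros.
* Neuron counts are normalized to gut length and expressed per 100 μm.
* Dunnett many-to-one comparisons are computed by Monte Carlo: the null
  maximum-|t| distribution is sampled (default 1e5 draws) with the shared
  control mean and pooled variance resampled, preserving the comparisons'
  correlation under equal variances. This avoids a multivariate-t
  quadrature dependency and is validated in the tests against the
  `multcomp` reference and against the single-treatment reduction.

## Candidate selection

A (patient, gene) pair is emitted iff the CNV is rare **and** loss-like,
the gene overlaps it, is an ENS gene, is a CCR, and has at least one
zebrafish orthologue (a/b duplicates are both reported, since paralog pairs
are targeted simultaneously in vivo). Genes whose ENS status could not be
evaluated — no mouse orthologue or no probes — are excluded from candidacy
but listed separately: unevaluable is not negative. Duplicates from
overlapping CNVs in one patient are collapsed per (patient, gene). The
report bundle (per-sample burden, group statistics, candidate table,
run-metadata JSON echoing thresholds and seed) is byte-deterministic for a
fixed configuration.

## The synthetic-data generator

The generator emulates the *structure* of the study, not its exact data:

* **Genome and genes.** Two chromosomes (60 + 40 Mb) tiled with 2,000
  non-overlapping gene/transcript models (~1 per 50 kb). The density is
  transcript-level rather than protein-coding-gene-level because the
  emulated analysis counts every impacted gene *or transcript* (microRNA,
  lncRNA included).
* **CNVs.** Poisson 2 calls/sample; log10 sizes Normal(5, 0.4) — median
  100 kb — floored at the 20 kb detection limit of the emulated arrays;
  48% losses, 48% gains, 4% homozygous losses. Group-1 losses are scaled by
  `planted_loss_size_multiplier` (default 10), reproducing the study
  condition of multi-megabase losses in the anomaly group. Sizes are
  truncated at the largest chromosome length — a CNV cannot exceed its
  chromosome, and whole-chromosome aneuploidy is out of scope.
* **Common CNVs.** A fraction (default 0.2) of case CNVs is copied into
  four distinct control samples with endpoints jittered by at most ±10% of
  the size — which guarantees ≥ 75% mutual overlap between any two copies —
  so the planted calls classify as common from both the case and the
  control side (a common variant must be common among controls too, or the
  control arm of the burden analysis would inherit "rare" copies of the
  largest case losses).
* **Expression.** Planted ENS genes (default fraction 0.25, close to the
  evaluable ENS fraction of the emulated study) carry a log2(fold) offset
  (default fold 4) in both ENS classes, Gaussian noise sd 0.25 on the log2
  scale, 5 samples per class and 5% missing-at-random values. Only genes
  with a mouse orthologue (default 60%) get expression rows — the rest are
  unevaluable downstream, as in the real analysis.
* **Genotypes and phenotypes.** Hardy–Weinberg risk-allele counts at the
  six SNPs; multinomial category I–V counts per condition.

One master seed feeds fixed per-generator offsets, so each input can be
regenerated independently and byte-identically.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage between risk SNPs, locus-specific
gene density and CNV hotspots, array probe-level noise and GC waves,
segmentation/breakpoint error, correlated missingness in expression data,
and any dependence between a gene's constraint and its expression. The
recovery criteria (ENS recall, burden significance rates) are statements
about the pipeline's operating characteristics under this generative model,
not about any particular cohort.

## Problem sizes and numerical conventions

The verification suite uses these sizes, chosen to make sampling error
small relative to the tolerances: per-base brute-force oracles on 100
random ≤ 10 kb toy genomes for the interval machinery; 5,000
model-simulated variances for prior recovery (10% tolerance); 2,000 genes
for the type-I error of the moderated t (0.05 ± 0.01); exhaustive
vs Monte-Carlo permutation agreement within 0.02 on a 3-vs-3 toy; ENS
recovery at 2,000 genes, fold 4, noise 0.25 (recall > 0.9, false-positive
rate < 0.01); and 50 replicate cohorts for the burden recovery (both
group-1 signals at p < 0.01 in > 95%).

Ties in quantile normalization receive the mean of their tied ranks'
targets; the RVM optimizer works on log-parameters so positivity is
structural; z-scores refuse zero-variance reference sets; the N-1
chi-squared refuses zero margins; interval containers refuse empty
intervals. All stochastic procedures take explicit integer seeds.

## Known limitations

* The rarity classifier assumes control calls are comparable in resolution
  to case calls; real cross-platform frequency lookups need liftover and
  size harmonization that are out of scope.
* The RVM assumes a single global variance prior; strong mean–variance
  trends would call for a local fit.
* The Dunnett adjustment assumes equal variances; unequal-variance designs
  should use the Welch flag with per-pair tests instead.
* Candidate selection is gene-level: exon-aware intersection and regulatory
  elements are not modelled.
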