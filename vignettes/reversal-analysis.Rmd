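---
title: "Treatment-reversal analysis of kidney single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment-reversal analysis of kidney single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screverse)
```

# The question and the model

`screverse` formalizes a three-group treatment-reversal design. A cohort
contains healthy controls (HC), untreated disease (T2Di−) and treated
disease (T2Di+); the scientific question is which transcripts the treatment
pushes back toward the control state, resolved by kidney tubular segment
(PT, DTL, TAL, IC, PC).

## Differential expression

Expression is analyzed on the log2 scale,
`log2(1 + scale * count / library)`. For each segment, each gene is fitted
with ordinary least squares on a two-group indicator, separately for the two
contrasts:

* disease: β₁ = mean(T2Di−) − mean(HC)
* treatment: β₂ = mean(T2Di+) − mean(T2Di−)

Gene-wise residual variances s² (on d residual degrees of freedom) are
shrunk toward a common prior with the standard empirical-Bayes scheme: the
prior (s₀², d₀) is estimated by the method of moments on log s² — the excess
of var(log s²) over trigamma(d/2) is inverted through the trigamma function
(Newton iteration, relative tolerance 1e−10) to give d₀, with d₀ = ∞ when
the moment equation has no solution — and the posterior variance is
s̃² = (d₀ s₀² + d s²) / (d₀ + d). The moderated t = β / (s̃ √(1/n₁ + 1/n₂))
is referred to a t distribution on d₀ + d degrees of freedom (the normal
limit at d₀ = ∞). Both limits are contractual and tested: at d₀ = 0 the
statistic is the ordinary two-sample t, at d₀ = ∞ all genes share the prior
variance. Genes with zero variance across the tested units are flagged
untestable and excluded from testing and from the multiple-testing family.

P values are adjusted by the Benjamini–Hochberg step-up procedure *within
each (contrast, segment) gene list*. The per-segment family matches how
reversal is declared and counted (per segment); adjusting across all
segments jointly would couple segments with very different signal densities.
This family choice is a design decision — a joint family is defensible too —
and is the main knob that moves absolute reversal counts.

## The reversal classifier

With α = 0.05 (configurable), a gene in a segment is

* **suppressed**: FDR₁ < α ∧ FDR₂ < α ∧ β₁ > 0 ∧ β₂ < 0,
* **enhanced**: FDR₁ < α ∧ FDR₂ < α ∧ β₁ < 0 ∧ β₂ > 0,
* **not_reversed** otherwise.

All inequalities are strict: a gene at FDR exactly α is not significant, and
a fold change of exactly 0 fails both sign gates. Significant *concordant*
pairs (same sign in both contrasts) are recorded as not reversed but exported
in a side table, since they describe progression rather than reversal. The
classifier is a pure function of (β₁, FDR₁, β₂, FDR₂, α) and is tested
against an exhaustive enumeration over sign × significance states, including
the FDR = α boundary. Cross-segment structure is summarized by upset-style
*exclusive* intersections, which partition the union of reversed genes — the
partition property is asserted in tests.

## Enrichment

Suppressed and enhanced lists are tested per segment with the one-sided
Fisher over-representation test, computed as the hypergeometric upper tail
of the 2×2 table (k, n−k, K−k, N−n−K+k). A pathway is reported significant
when p < 0.05 and it shares at least 5 transcripts with the query; queries
smaller than that minimum are skipped with a logged note (segments often
have too few enhanced transcripts to test). No multiple-testing correction
is applied across pathways — the significance rule is deliberately the
simple p/overlap gate. The default background universe is the set of genes
tested for differential expression in that segment, which conditions on
testability; a `universe_mode = "global"` (union of collection members)
mirrors tools that use a fixed annotation-wide background and generally
yields smaller p values. The difference matters when the tested panel is
much smaller than the annotation.

## Pathway scoring

Single-sample scores use the rank-weighted ssGSEA running sum: per unit,
genes are ranked by expression (average ranks on ties), walked in decreasing
rank; in-set steps add rank^α normalized to sum 1 over in-set genes
(α = 0.25 by default, the customary exponent; α = 0 weights all in-set genes
equally), out-of-set steps add 1/(G − m); the score is the sum of the running
difference. Being rank-based, scores are invariant to any strictly monotone
per-unit transform; ties in the walk order are broken by gene name so scores
are deterministic. No cross-unit min–max normalization is applied by
default — the Δ statistic below is a within-cohort difference, and scores
from differently sized gene universes should not be compared anyway.

Scoring happens per cell by default. Scores are averaged within
(donor, segment), then across donors per (group, segment), and
Δ = group mean − HC mean, so Δ(HC) = 0 by construction and donors — not
cells — are the replication unit. A pseudobulk scoring mode exists for
sparse nuclei data; on simulated cohorts the two modes agree in the sign of
Δ (tested).

# What the simulator emulates — and what it does not

`simulate_cohort()` draws counts from a negative binomial with
variance μ + φμ² (φ is the inverse-size parameter; `dispersion = 0.3` is a
typical single-cell value). Per-gene baseline means are log-normal
(`mu_meanlog = log(0.5)`, `mu_sdlog = 1`, i.e. a median of 0.5 counts per
cell across a 2,000-gene panel), cells carry log-normal library-size factors
(`libsize_sdlog = 0.15`), segment markers are enriched `marker_fold = 8`
within their segment, and 2% of genes are named with the `MT-` prefix so the
mitochondrial QC rule is exercised. The default design is 6 HC, 6 untreated
and 10 treated donors with 50 cells per donor per segment — the group sizes
follow the motivating human cohort; the per-segment cell count is a
desk-scale choice, not an empirical one.

Planted effects define the ground truth: suppressed-class genes are shifted
+δ log2 in untreated disease and retain δ(1 − ρ) under treatment (ρ is the
restoration fraction; ρ < 1 leaves residual disease effect, matching the
observation that reversed transcripts rarely return fully to control
levels); enhanced-class genes mirror this. A designated pathway set (39
genes by default, the size of the packaged synthetic mTORC1 stand-in)
receives its own coordinated suppressed-type shift so pathway scores have a
known group ordering. Group effects apply uniformly across segments — the
generator has no segment-by-treatment interaction — so per-gene truth is
constant across segments.

The bulk mode (`simulate_bulk_cortex()`, 5 samples per group, murine group
labels) uses the same planted structure with `bulk_dispersion = 0.05`: bulk
profiles average over very many cells, so their biological coefficient of
variation is far below single-cell dispersion.

Deliberately not modeled: doublets, ambient RNA, batch effects, donor random
effects beyond library size, segment-specific treatment responses, and
mean–dispersion trends. Passing tests therefore demonstrate that the
pipeline recovers planted structure under clean NB sampling — they do not
certify performance against ambient contamination or confounded designs.

# Numerical and design choices

* **QC bounds**: detected-gene bounds are inclusive (a 500-gene cell is
  kept), the mitochondrial rule is strict (a cell at exactly 50% is
  removed), matching "between 500 and 5,000" and "fewer than 50%" semantics.
  QC is idempotent; an empty input is a warning, not an error.
* **Replication unit**: differential expression runs on pseudobulk sums per
  (donor, segment) by default, respecting the donor as the unit of
  replication; a cell-level mode exists for sensitivity analysis and is
  expected to be anti-conservative (cells within a donor are not
  independent).
* **Normalization**: log2(1 + CP10K) everywhere. On pseudobulk profiles the
  +1 offset at the 1e4 scale corresponds to an effective prior count of
  (library/1e4) ≈ 5–10, which damps the log-scale variance of low-count
  genes and markedly improves the stability of the variance moderation
  (estimated d₀ rises roughly tenfold versus a counts-per-million scale).
  The log2FC is then mildly shrunk toward 0 for weakly expressed genes — a
  deliberate bias/variance trade.
* **Marker scores**: per-gene z-scores across cells; zero-variance genes
  contribute 0; assignment is argmax with ties broken by panel declaration
  order, so annotation is deterministic.
* **Segment assignment** replaces graph clustering + manual annotation: on
  simulated data at 8-fold marker enrichment it agrees with planted labels
  in ≳ 95% of cells. It is a stand-in, not a clustering method.
* **Hypergeometric tail**: computed with `phyper(k − 1, ...)`; the odds
  ratio reported is the sample odds ratio of the 2×2 table (Inf for empty
  off-diagonal cells), not the conditional MLE.
* **Determinism**: every stochastic stage is driven by a single integer seed
  (`withr::with_seed`), and identical config + seed reproduces the run
  summary byte for byte.

# Problem sizes used by the test suite

Unit tests run on miniature fixtures (tens of genes). The acceptance-style
integration tests use the study-sized configuration — 2,000 genes, five
segments, 6/6/10 donors, 50 cells per donor per segment — with 10 simulated
null cohorts for calibration (mean reversed calls per segment ≤ 5) and one
planted cohort each for recovery (sensitivity ≥ 0.8, precision ≥ 0.9 for the
reversed class; the planted pathway ranks first in every segment's
suppressed enrichment) and for Δ-score ordering (treated below untreated in
all five segments at ρ = 0.8). These sizes were chosen so the whole suite
runs on a laptop in a few minutes while keeping per-segment pseudobulk
replication at the cohort's actual donor counts.

# Known limitations

* The moderated model assumes exchangeable gene-wise variances around a
  single prior; strong mean–variance trends (very deep or very shallow
  libraries) would call for a trend-aware prior, which is not implemented.
* No covariate adjustment (age, sex, batch) and no random effects; designs
  where treatment is confounded with batch will produce confounded
  reversals.
* The enrichment stage tests over-representation only; it does not model
  inter-gene correlation, so planted-style coordinated sets make its p
  values optimistic relative to a competitive test.
* Δ pathway scores are descriptive (means with sample-level dispersion); the
  package intentionally reports no significance test for Δ.
* Mouse–human gene matching is plain symbol matching (optionally
  case-folded); no ortholog mapping is attempted.
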