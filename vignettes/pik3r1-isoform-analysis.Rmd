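---
title: "Isoform-level PIK3R1 analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-level PIK3R1 analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pik3r1iso)
```

## The measurement model

*PIK3R1* produces two isoforms by alternative first-exon usage: the
full-length regulatory subunit p85α and the shorter p55α. Their mRNAs share
the downstream exons, so isoform abundance is read off the one splice
junction unique to each isoform. A junction is identified by the intron it
evidences — chromosome, first and last intronic base, strand — and we use
1-based fully closed coordinates throughout, the convention of
recount3-style junction exports. The two discriminating junctions are
`chr5:68281007-68292258:+` (p85α) and `chr5:68290835-68292258:+` (p55α),
sharing their acceptor at 68,292,258 (hg38).

Quantification is **exact-key matching**: a junction row contributes to an
isoform only if its (chrom, start, end, strand) equals a discriminating
junction exactly, strand included. Positional overlap would double-count
reads from the other isoform's junction, which differs only in its donor.
A discriminating junction absent from a matrix contributes zero, so a
sample with no spliced reads for an isoform gets raw count 0 rather than a
missing value — this matters because the p55α grouping rule tests raw
counts against exactly 0.

Log expression is `log10(x + 1)`. Base 10 matches the scale on which the
expression distributions are usually displayed; the +1 pseudocount is the
smallest choice that maps 0 to 0 and keeps the transform strictly
increasing, and it is exposed as a parameter for sensitivity checks.

Two printed coordinate systems coexist in this analysis and disagree by
one base at the interval ends (68281007 vs 68,281,006; 68292258 vs
68,292,259) and in ordering. We deliberately do not reconcile them:
quantification uses the junction coordinates verbatim, and variant-region
classification uses the region coordinates verbatim (normalized to
genomic order, since an interval printed 5'→3' of a minus-strand
transcript runs backwards genomically). Silently "fixing" either would
make the package disagree with the source of whichever coordinate a user
checks.

## Stratification rules

Two grouping rules, each matched to the distribution it splits:

- **Mean split** (p85α): within one cancer type's tumor samples, threshold
  at the arithmetic mean of log10 expression; 'high' iff strictly above.
  Log scale is used because every displayed quantity is on the log scale;
  the per-cancer scope reflects that survival models are fitted per
  cancer. Both scale and scope are configurable, since neither is forced
  by the data. A value exactly at the mean is 'low' — a measure-zero event
  on log data, but a deterministic tie-break keeps reruns identical.
- **Zero/non-zero** (p55α): 'low' iff the raw count is exactly 0. This
  rule presupposes a point mass at zero, which is why the synthetic
  generator uses a zero-inflated count model for p55α.

Race strings are normalized case-insensitively through a small synonym
table ("black or african american" → AA, "white" → EA, extendable).
Anything else becomes `NA-other`: retained in cohort partitions, excluded
from AA/EA group tests. This mirrors the analysis situation where a small
third group (e.g. eleven Native American patients in the motivating
cohort) is too small for subgroup inference but should not silently
vanish from sample accounting.

## The statistics, from first principles

The group comparisons and survival models are the package's core, so they
are implemented directly rather than wrapped; `wilcox.test`, `aov`,
`TukeyHSD`, `survdiff` and `coxph` appear only as independent oracles in
the test suite.

**Wilcoxon rank-sum.** The tumor-vs-normal comparison is unpaired: group
sizes are unequal in every cohort, which is only consistent with the
two-sample rank-sum form. Exact mode enumerates all `choose(n1+n2, n1)`
assignments of the combined ranks (default bound n1+n2 ≤ 12, above which
enumeration buys nothing over the approximation); the approximate mode
uses the tie-corrected variance
`n1 n2/12 ((N+1) − Σ(t³−t)/(N(N−1)))` and a 0.5 continuity correction.
Exact mode with ties falls back to the approximation with a warning
rather than erroring, because tied data is the common case, not the
exception.

**One-way ANOVA and Tukey HSD.** F = MS_between/MS_within on (k−1, N−k)
df. The race comparison (normal vs AA tumor vs EA tumor) uses one-way
ANOVA; where the source material is ambiguous between one- and two-way
forms for protein correlations, the one-way form is implemented as the
primary path because it matches the displayed low/high contrasts, and the
choice is recorded here as a deliberate deviation. Zero within-group
variance is handled explicitly (equal means → F = 0, p = 1; unequal → p =
0) instead of producing NaN. Post-hoc pairwise contrasts use Tukey HSD
with the Tukey–Kramer standard error — chosen because pairwise
significance displays in this literature rarely name a procedure, and HSD
is the default a practitioner would assume; for k = 2 it reduces exactly
to the pooled t-test.

**Kaplan–Meier and log-rank.** The product-limit estimator with the
standard convention that censorings tied with an event time remain at
risk for those events. The log-rank statistic sums, per distinct event
time, observed minus hypergeometrically expected group event counts, and
forms the quadratic in the summed hypergeometric covariance ((O₁−E₁)²/V
for two groups); a generalized inverse is used if the covariance is
singular. With no events at all the test returns p = 1 with a warning
rather than failing.

**Cox proportional hazards.** Newton–Raphson on the partial likelihood,
Efron tie correction by default (the default of the R `survival` package,
hence of most published TCGA analyses; Breslow by flag). Convergence is
declared at max |score| < 1e−9 (max 100 iterations, with step-halving if
a full step decreases the likelihood). Wald 95% CIs are β ± 1.96·SE. A
coefficient passing |β| > 20 aborts with a separation error naming the
covariate — a monotone partial likelihood has no finite maximizer, and
reporting a huge "estimate" would be worse than refusing. Covariate
encoding: age continuous; sex, race, smoking and alcohol one-hot against
the first alphabetical level unless configured; AJCC stage collapsed to
early (I/II) vs advanced (III/IV) because the adjusted models report a
single stage contrast. Missing covariates are handled by complete-case
deletion with the dropped count recorded. Covariates that become constant
after deletion are dropped from the design rather than crashing the fit.

## The synthetic cohort generator

The generator's defaults are the study conditions the package is tested
under, chosen once:

| parameter | default | rationale |
|---|---|---|
| n_tumor / n_normal | 100 / 100 | typical per-cancer TCGA normal-paired scale |
| p85α: NB mean (normals), log2 tumor shift, dispersion | 120, −1, 2 | moderately expressed junction; a halving in tumors; overdispersion typical of junction counts |
| p55α: zero probability normals/tumors, NB mean, dispersion | 0.70 / 0.35, 25, 1.5 | point mass at zero dominant in normals, halved in tumors; low counts when expressed |
| race mixture | AA 0.25, EA 0.70, other 0.05 | AA/EA-focused cohort with a small third group to exercise the exclusion path |
| survival | exponential, λ₀ = 5·10⁻⁴/day; β: ln 2 (low-p85α), 0.02/yr (age), 0.5 (advanced stage), 0 (race) | constant baseline hazard allows closed-form checks (S(t) = e^(−λ₀t)); the group effect is a doubling of hazard |
| censoring | uniform(0, 3650 days) | administrative-style right censoring over a ten-year window |
| protein effects | AKT_pS473 −0.8, mTOR_pS2448 −0.6, PTEN +0.7 (high-p85α group), SD 1 | phospho-AKT/mTOR lower and PTEN higher when the regulatory isoform is high |

Draws come from five per-component streams (clinical, junctions,
survival, protein, variants), each seeded by a sub-seed derived once from
the master seed, so the components are independent and identical
configurations reproduce byte-identical integer tables. The survival
linear predictor uses the low/high p85α label **derived from the
simulated counts by the mean-split rule** — the covariate the pipeline
will actually reconstruct — so end-to-end recovery tests exercise the
full path from counts to hazard ratios.

What the generator does *not* emulate: batch structure, library-size
variation between samples, correlated junctions within a gene, real
allele frequencies, non-proportional hazards, or informative censoring.
Passing tests therefore demonstrate correctness of the computations and
calibration of the tests under the stated model, not robustness to the
messiness of real TCGA data.

The planted variant fixture places region-specific variants strictly
inside one region and "shared" variants at the single coordinate common
to both printed region intervals (68,290,834) — the two intervals overlap
in exactly one base, so that is the only position a shared variant can
occupy under closed-interval containment. Each fixture also carries a toy
CDS whose codon 6 is TGG with the c.18G>T substitution, the
tryptophan→cysteine missense worked example.

## Numerical and degenerate-input choices

- Exact Wilcoxon p-values are multiples of 1/`choose(n1+n2, n1)`;
  two-sided p is twice the smaller tail, capped at 1.
- ANOVA/Tukey with zero residual variance short-circuits to {0, 1} / {Inf, 0}.
- The log-rank covariance uses `solve` with a `MASS::ginv` fallback.
- Cox convergence: max |score| < 1e−9; the test suite additionally checks
  max |score| < 1e−6 at every reported optimum and the classical
  equivalence of the score test at β = 0 with the log-rank χ² (to 1e−8).
- Junction parsing accepts ASCII and Unicode dashes and digit-grouping
  commas (publication typography); reversed intervals are swapped with a
  warning, never silently.
- Duplicate junction keys within one file are an error (corrupt input),
  not summed.
- Unknown consequence strings are downgraded to `other` with a warning,
  never dropped.
- The genetic code table is defined in-package (the annotator is core
  functionality) and verified codon-by-codon against
  `Biostrings::GENETIC_CODE` in the test suite, as is the whole annotator
  against a retranslate-the-mutated-CDS oracle over 1000 random SNVs.

## Open choices resolved

- **Count column**: junction readers expose `count_column =
  "unique"`/`"total"` for the STAR format; unique reads are the default,
  matching the "unique junction counts" a recount3-style export provides.
- **Mean-split scope**: per cancer type (configurable), since survival
  stratification operates per cancer.
- **Multiple testing**: raw p-values by default, with a Benjamini–Hochberg
  switch in the pipeline config; no correction is applied silently.
- **Pipeline shape**: the orchestrator (`run_pipeline`) runs each cancer
  type independently and records failures per cancer instead of aborting,
  because cohorts legitimately differ in which stages they can support
  (e.g. no normals, too few events).

## Problem sizes used by the test suite

The suite runs the Monte-Carlo calibrations at 10,000 replicates for the
Wilcoxon (n = 20/20) and ANOVA (k = 3 × n = 15) null rejection rates and
5,000 replicates for the log-rank (n = 200/200, ~30% censoring), Cox
recovery at n = 300 over 200 replicates, and the end-to-end isoform-switch
detection at n = 100/100 over 200 generator seeds — sizes at which the
binomial error of a rejection-rate estimate (±0.004 at 10,000 reps) is
well inside the ±0.01 acceptance band.

## Known limitations

- Junction counts are not library-size normalized; the analyses operate
  on log counts as published, which is defensible for within-cancer
  tumor/normal contrasts but not across studies.
- No proportional-hazards diagnostics beyond this caveat; the Cox model
  is taken at face value as in the source analysis.
- The coding-SNV annotator handles single-nucleotide substitutions only
  (no indels/frameshifts), matching its role of annotating SNVs.
- The variant module reproduces the *structure* of a per-isoform variant
  summary (classes × regions, shared variants); the published gnomAD
  totals depend on that database's query semantics and are validated here
  on planted synthetic fixtures instead.
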