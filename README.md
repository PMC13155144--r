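# pik3r1iso

Pan-cancer analysis of the two alternative-first-exon isoforms of
*PIK3R1* — the full-length PI3K regulatory subunit **p85α** and its shorter
splicing variant **p55α** — from splice-junction read counts, with the
downstream group-comparison, survival, protein-correlation and
variant-annotation analyses implemented as a reusable, tested R package.

## The scientific problem

*PIK3R1* encodes p85α, the regulatory subunit that restrains the p110α
catalytic subunit of class IA PI3K; alternative first-exon usage produces
the shorter p55α. In tumors the balance shifts: p85α is downregulated
(consistent with a tumor-suppressive role) while p55α is more often
expressed, and low p85α expression associates with worse overall survival
(OS) and progression-free interval (PFI) in several cancers, with effect
sizes that differ between African American (AA) and European American (EA)
patients.

Because the two isoforms share most of their exons, whole-gene read counts
cannot separate them. Each isoform is instead measured by its
**discriminating splice junction** — a junction present in exactly one
isoform, so its read count measures that isoform alone:

| isoform | discriminating junction (hg38, intron span) |
|---|---|
| p85α | `chr5:68281007-68292258:+` |
| p55α | `chr5:68290835-68292258:+` |

The two junctions share their acceptor coordinate (68,292,258). Raw
expression of an isoform in a sample is the sum of junction reads at its
discriminating junction(s); log expression is `log10(x + 1)`.

The package implements, from first principles where the method is the
point:

- **Quantification** — junction string parsing, junction-TSV and STAR
  `SJ.out.tab` readers, exact-key junction matching, per-cancer expression
  CSVs.
- **Stratification** — the two published grouping rules: mean split of
  log p85α expression within a cancer's tumors ('high' iff strictly above
  the mean), and the zero/non-zero rule for p55α ('low' iff raw count is
  exactly 0); race normalization to AA/EA with other groups retained but
  excluded from tests.
- **Group statistics** — Wilcoxon rank-sum (exact enumeration for small
  tie-free samples, tie-corrected normal approximation otherwise), one-way
  ANOVA with Tukey HSD post-hoc, the 2^−ΔΔCt qRT-PCR fold change, and
  protein-by-group comparisons.
- **Survival** — Kaplan–Meier product-limit estimation, the k-sample
  log-rank test with hypergeometric variance, and Cox proportional-hazards
  regression maximizing the partial likelihood by Newton–Raphson with
  Efron (default) or Breslow tie handling; forest-style HR tables with the
  four-tier significance stars.
- **Variant annotation** — region classification against the
  isoform-specific intervals (5:68,281,006–68,290,834 for p85α,
  5:68,290,834–68,292,259 for p55α, closed intervals), consequence-class
  tallies per region with shared-variant detection, and a codon-level
  coding-SNV annotator producing HGVS p. strings (e.g. `c.18G>T` in a CDS
  whose codon 6 is TGG → `p.Trp6Cys`, missense).
- **Synthetic cohorts** — a seeded generator (negative-binomial p85α
  counts with a tumor log2 shift, zero-inflated negative-binomial p55α,
  exponential proportional-hazards survival, group-shifted protein values,
  planted variant tables) so every stage is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated two-cancer cohort (seed 1, 100 tumors / 100 normals each, p85α
shifted −1 log2 unit in tumors, p55α zero-probability 0.70 in normals vs
0.35 in tumors):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_quantify_isoforms.R
Rscript analysis/03_group_statistics.R
Rscript analysis/04_survival_analysis.R
Rscript analysis/05_variant_annotation.R
Rscript analysis/06_full_pipeline.R
```

Step 03 prints, for example:

```
SIMA p85a: Wilcoxon p = 4.15e-09 (tumor_down); race ANOVA F = 17.52, p = 1.01e-07
SIMA p55a: Wilcoxon p = 5.58e-05 (tumor_up); race ANOVA F = 7.77, p = 0.000568
```

i.e. the planted isoform switch is detected in the expected direction —
p85α lower and p55α higher in tumors — and the three-group comparison
(normal vs AA tumor vs EA tumor) is significant. Step 04 prints the
survival summary per cancer and endpoint:

```
SIMA PFI: log-rank chisq = 25.70 (p = 4e-07); low-p85a HR = 3.88 [2.28, 6.61] ****; 3-yr S: low 0.06 vs high 0.41
```

the hazard ratio being the multivariate Cox estimate for the low-p85α
group adjusted for age, sex, race, stage, smoking and alcohol history.
Step 05 recovers the planted variant tally exactly and annotates the
coding-SNV example:

```
coding SNV c.18G>T on the toy CDS: p.Trp6Cys (missense, codon 6)
```

Equivalent calls in R:

```r
library(pik3r1iso)
co <- simulate_cohort(sim_config(seed = 1))
et <- quantify_isoforms(co$junctions, pik3r1_isoforms())
ann <- annotate_coding_snv("ATGGCTGAAGATCTATGGTCAGGCTAA", 18, "G", "T")
ann$hgvs_p   # "p.Trp6Cys"
```

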