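#!/usr/bin/env Rscript
# Tumor-vs-normal Wilcoxon tests per isoform and cancer type, race-group
# one-way ANOVA (normal vs AA tumor vs EA tumor) with Tukey post-hoc, and
# protein-by-isoform-group comparisons.

library(pik3r1iso)

clin <- read.csv("results/cohort/clinical.csv", stringsAsFactors = FALSE)
prot <- read.csv("results/cohort/protein.csv", stringsAsFactors = FALSE)
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

rows <- list()
all_labels <- list()
for (cc in sort(unique(clin$type))) {
  et <- read_expression_csv(file.path("results/expression",
                                      paste0(cc, ".csv")))
  tum <- et$sample_type == "tumor"
  lab85 <- split_by_mean(et$p85a_log[tum], et$sample_barcode[tum])
  all_labels[[cc]] <- lab85
  cohorts <- build_cohorts(clin[clin$type == cc, ], lab85)
  for (iso in c("p85a", "p55a")) {
    lg <- et[[paste0(iso, "_log")]]
    w <- wilcoxon_rank_sum(lg[tum], lg[!tum])
    rows[[paste(cc, iso)]] <- data.frame(
      cancer = cc, isoform = iso, statistic = unname(w$statistic),
      p_value = w$p_value,
      direction = ifelse(mean(lg[tum]) < mean(lg[!tum]),
                         "tumor_down", "tumor_up"))
    grp <- list(normal = lg[!tum],
                AA_tumor = lg[tum][cohorts$race[tum] == "AA"],
                EA_tumor = lg[tum][cohorts$race[tum] == "EA"])
    grp <- grp[lengths(grp) >= 2]
    if (length(grp) >= 2) {
      an <- oneway_anova(grp)
      cat(sprintf("%s %s: Wilcoxon p = %.3g (%s); race ANOVA F = %.2f, p = %.3g\n",
                  cc, iso, w$p_value, rows[[paste(cc, iso)]]$direction,
                  unname(an$statistic), an$p_value))
    }
  }
}
write.csv(do.call(rbind, rows), "results/stats/tumor_vs_normal.csv",
          row.names = FALSE)

pres <- protein_by_group(prot, do.call(rbind, all_labels))
write.csv(pres, "results/stats/protein_by_group.csv", row.names = FALSE)
cat("\nProtein-by-group (low vs high p85a):\n")
print(pres)
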