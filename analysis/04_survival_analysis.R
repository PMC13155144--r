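#!/usr/bin/env Rscript
# Survival analysis per cancer type: Kaplan-Meier curves for low vs high
# p85a expression, two-group log-rank tests, and multivariate Cox models
# (Efron ties) adjusting for age, sex, race, stage, smoking and alcohol
# history, for both overall survival and progression-free interval.

library(pik3r1iso)

clin <- read.csv("results/cohort/clinical.csv", stringsAsFactors = FALSE)
dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)

for (cc in sort(unique(clin$type))) {
  et <- read_expression_csv(file.path("results/expression",
                                      paste0(cc, ".csv")))
  tum <- et$sample_type == "tumor"
  lab <- split_by_mean(et$p85a_log[tum], et$sample_barcode[tum])
  d <- clin[clin$type == cc & clin$sample_type == "tumor", ]
  d$group <- lab$label[match(d$bcr_patient_barcode, lab$barcode)]
  d$race_grp <- normalize_race(d$race)
  d$stage <- ifelse(d$ajcc_stage %in% c("Stage III", "Stage IV"),
                    "advanced", "early")
  for (ep in c("OS", "PFI")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    keep <- !is.na(d[[tcol]]) & d$race_grp != "NA-other"
    dd <- d[keep, ]
    lr <- logrank_test(dd[[tcol]], dd[[ecol]], dd$group)
    km_lo <- km_estimate(dd[[tcol]][dd$group == "low"],
                         dd[[ecol]][dd$group == "low"])
    km_hi <- km_estimate(dd[[tcol]][dd$group == "high"],
                         dd[[ecol]][dd$group == "high"])
    fit <- cox_fit(dd[[tcol]], dd[[ecol]],
                   dd[, c("group", "age", "gender", "race_grp", "stage",
                          "smoking_history", "alcohol_history")],
                   reference = list(group = "high", stage = "early"))
    tab <- forest_table(fit)
    write.csv(tab, file.path("results/survival",
                             sprintf("cox_%s_%s.csv", cc, ep)),
              row.names = FALSE)
    grp_row <- tab[tab$term == "group_low", ]
    cat(sprintf("%s %s: log-rank chisq = %.2f (p = %.3g); low-p85a HR = %.2f [%.2f, %.2f]%s; 3-yr S: low %.2f vs high %.2f\n",
                cc, ep, unname(lr$statistic), lr$p_value, grp_row$HR,
                grp_row$ci_low, grp_row$ci_high,
                ifelse(nzchar(grp_row$stars),
                       paste0(" ", grp_row$stars), ""),
                km_survival_at(km_lo, 1095), km_survival_at(km_hi, 1095)))
  }
}
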