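#!/usr/bin/env Rscript
# Quantify p85a and p55a expression per sample from the junction matrix:
# raw counts at each isoform's discriminating junction and log10(x + 1)
# expression, written per cancer type as CSV.

library(pik3r1iso)

jm <- read_junction_matrix("results/cohort/junctions.tsv", format = "tsv")
clin <- read.csv("results/cohort/clinical.csv", stringsAsFactors = FALSE)

et <- quantify_isoforms(jm, pik3r1_isoforms(),
                        sample_type = setNames(clin$sample_type,
                                               clin$bcr_patient_barcode))
dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)
for (cc in sort(unique(clin$type))) {
  bc <- clin$bcr_patient_barcode[clin$type == cc]
  sub <- et[et$sample_barcode %in% bc, ]
  write_expression_csv(sub, file.path("results/expression",
                                      paste0(cc, ".csv")))
  tum <- sub$sample_type == "tumor"
  cat(sprintf("%s: %d tumor / %d normal; mean log10 p85a %0.3f (T) vs %0.3f (N); p55a nonzero %0.0f%% (T) vs %0.0f%% (N)\n",
              cc, sum(tum), sum(!tum),
              mean(sub$p85a_log[tum]), mean(sub$p85a_log[!tum]),
              100 * mean(sub$p55a_raw[tum] > 0),
              100 * mean(sub$p55a_raw[!tum] > 0)))
}
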