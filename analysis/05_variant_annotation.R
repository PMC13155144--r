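#!/usr/bin/env Rscript
# Classify the variant table into the p85a / p55a isoform regions, tally
# consequence classes per region, list shared variants, and annotate the
# worked coding-SNV example (G>T at coding position 18 of a CDS whose codon
# 6 is the tryptophan codon TGG).

library(pik3r1iso)

v <- read_variants("results/cohort/variants.tsv", format = "tsv")
tally <- tally_consequences(v, pik3r1_regions())
dir.create("results/variants", showWarnings = FALSE, recursive = TRUE)
write_tally_csv(tally, "results/variants/tally.csv")

print(tally)
cat("shared rsIDs:", paste(tally$shared, collapse = ", "), "\n\n")

cds <- "ATGGCTGAAGATCTATGGTCAGGCTAA"
ann <- annotate_coding_snv(cds, coding_pos = 18, ref = "G", alt = "T")
cat("coding SNV c.18G>T on the toy CDS:", ann$hgvs_p,
    paste0("(", ann$category, ", codon ", ann$codon_index, ")"), "\n")
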