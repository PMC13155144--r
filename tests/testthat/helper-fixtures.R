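# fixtures built in code; no binary files

# small junction matrix containing the two PIK3R1 discriminating junctions
# plus a decoy on the opposite strand
make_test_jm <- function(counts85 = c(12, 0), counts55 = c(0, 7),
                         samples = c("S1", "S2")) {
  jdf <- data.frame(
    chrom = c("chr5", "chr5", "chr5"),
    start = c(68281007, 68290835, 68281007),
    end = c(68292258, 68292258, 68292258),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  junction_matrix(jdf, rbind(counts85, counts55, rep(99, length(samples))),
                  samples)
}

make_test_clinical <- function(barcodes, cancer = "TST",
                               sample_type = "tumor",
                               race = "white") {
  n <- length(barcodes)
  data.frame(bcr_patient_barcode = barcodes, type = cancer,
             sample_type = rep_len(sample_type, n),
             race = rep_len(race, n), stringsAsFactors = FALSE)
}

# random CDS of n_codons codons: starts ATG, no internal stops, ends with a
# stop codon
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(pik3r1iso:::GENETIC_CODE_DNA)
  sense <- setdiff(codons, stops)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}
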