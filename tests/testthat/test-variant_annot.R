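test_that("variant TSV and VCF readers produce normalized records", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "v.tsv")
  writeLines(c("chrom\tpos\tref\talt\trsid\tconsequence",
               "5\t68285000\tA\tG\trs1\tintron variant",
               "5\t68291000\tC\tT\trs2\t5' UTR"), tsv)
  v <- read_variants(tsv, format = "tsv")
  expect_equal(nrow(v), 2L)
  expect_equal(v$consequence, c("intron", "5_prime_UTR"))
  # minimal VCF: one row, and one multi-allelic row split into two records
  vcf <- file.path(d, "v.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "5\t68285000\trs1\tA\tG\t.\tPASS\tCSQ=missense",
               "5\t68291000\trs2\tC\tA,T\t.\tPASS\tCSQ=intron"), vcf)
  vv <- read_variants(vcf, format = "vcf")
  expect_equal(nrow(vv), 3L)
  expect_equal(vv$alt, c("G", "A", "T"))
  expect_equal(vv$consequence, c("missense", "intron", "intron"))
  expect_equal(vv$rsid, c("rs1", "rs2", "rs2"))
})

test_that("degenerate variant rows are rejected or downgraded", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "v.tsv")
  writeLines(c("chrom\tpos\tref\talt\trsid\tconsequence",
               "5\t100\tA\tA\trs1\tintron"), tsv)
  expect_error(read_variants(tsv, format = "tsv"), "ref == alt")
  writeLines(c("chrom\tpos\tref\talt\trsid\tconsequence",
               "5\txyz\tA\tG\trs1\tintron"), tsv)
  expect_error(read_variants(tsv, format = "tsv"), "row 1")
  writeLines(c("chrom\tpos\tref\talt\trsid\tconsequence",
               "5\t100\tA\tG\trs1\tweird_annotation"), tsv)
  expect_warning(v <- read_variants(tsv, format = "tsv"), "weird")
  expect_equal(v$consequence, "other")
})

test_that("region classification uses closed intervals and partitions", {
  regions <- pik3r1_regions()
  # inside the p85a-specific span only
  expect_equal(classify_region(data.frame(chrom = "5", pos = 68285000),
                               regions), "p85a_only")
  # the single coordinate common to both intervals
  expect_equal(classify_region(data.frame(chrom = "5", pos = 68290834),
                               regions), "shared")
  # boundary positions are inside (closed interval)
  expect_equal(classify_region(data.frame(chrom = "5", pos = 68281006),
                               regions), "p85a_only")
  expect_equal(classify_region(data.frame(chrom = "5", pos = 68292259),
                               regions), "p55a_only")
  expect_equal(classify_region(data.frame(chrom = "5", pos = 1), regions),
               "outside")
  expect_warning(
    m <- classify_region(data.frame(chrom = "7", pos = 68285000), regions),
    "other chromosome")
  expect_equal(m, "outside")
  # the four membership classes partition any variant set
  set.seed(51)
  pos <- sample(68270000:68300000, 500, replace = TRUE)
  mem <- classify_region(data.frame(chrom = "5", pos = pos), regions)
  expect_true(all(mem %in% c("p85a_only", "p55a_only", "shared",
                             "outside")))
  expect_equal(length(mem), 500L)
})

test_that("consequence tallies conserve counts and find shared rsIDs", {
  v <- data.frame(chrom = "5",
                  pos = c(68285000, 68286000, 68290834),
                  ref = "A", alt = "G",
                  rsid = c("rsA", "rsB", "rsC"),
                  consequence = c("intron", "intron", "splice_region"),
                  stringsAsFactors = FALSE)
  ta <- tally_consequences(v)
  expect_equal(unname(ta$counts["intron", ]), c(2, 0))
  expect_equal(unname(ta$counts["splice_region", ]), c(1, 1))
  expect_equal(unname(ta$totals), c(3, 1))
  expect_equal(ta$shared, "rsC")
  # conservation: class counts sum to the region total
  expect_equal(colSums(ta$counts), ta$totals)
  expect_lte(length(ta$shared), min(ta$totals))
  # empty input
  t0 <- tally_consequences(v[0, ])
  expect_true(all(t0$counts == 0))
  # CSV writer round trip of the counts
  path <- withr::local_tempfile(fileext = ".csv")
  write_tally_csv(ta, path)
  back <- read.csv(path)
  expect_equal(back$p85a[back$consequence == "intron"], 2)
  expect_equal(back$p85a[back$consequence == "total"], 3)
})

test_that("planted fixtures of random shape are recovered exactly", {
  set.seed(52)
  classes <- setdiff(consequence_classes(), "other")
  for (i in 1:50) {
    plant <- data.frame(
      region = sample(c("p85a_only", "p55a_only", "shared"), 3,
                      replace = TRUE),
      class = sample(classes, 3),
      n = sample(0:6, 3, replace = TRUE), stringsAsFactors = FALSE)
    fix <- planted_variant_fixture(plant)
    ta <- tally_consequences(fix$variants)
    for (cls in consequence_classes()) {
      expect_equal(unname(ta$counts[cls, "p85a"]),
                   sum(plant$n[plant$class == cls &
                               plant$region %in% c("p85a_only", "shared")]))
      expect_equal(unname(ta$counts[cls, "p55a"]),
                   sum(plant$n[plant$class == cls &
                               plant$region %in% c("p55a_only", "shared")]))
    }
    expect_equal(colSums(ta$counts), ta$totals)
  }
  # zero plants give an empty table
  none <- planted_variant_fixture(
    data.frame(region = "p85a_only", class = "intron", n = 0))
  expect_equal(nrow(none$variants), 0L)
  expect_error(planted_variant_fixture(
    data.frame(region = "nowhere", class = "intron", n = 1)),
    "unknown planted region")
})

test_that("the coding-SNV annotator reports the Trp6Cys worked example", {
  # codon 6 spans coding positions 16-18 and reads TGG (tryptophan)
  cds <- "ATGGCTGAAGATCTATGGTCAGGCTAA"
  expect_equal(substr(cds, 16, 18), "TGG")
  ann <- annotate_coding_snv(cds, 18, "G", "T")
  expect_equal(ann$hgvs_p, "p.Trp6Cys")
  expect_equal(ann$category, "missense")
  expect_equal(ann$codon_index, 6)
})

test_that("synonymous and stop-gain substitutions are categorized", {
  cds <- "ATGCTGTGGTAA"             # Met Leu Trp Ter
  syn <- annotate_coding_snv(cds, 6, "G", "A")   # CTG -> CTA, both Leu
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$hgvs_p, "p.(=)")
  stp <- annotate_coding_snv(cds, 8, "G", "A")   # TGG -> TAG stop
  expect_equal(stp$category, "stop_gained")
  expect_equal(stp$hgvs_p, "p.Trp3Ter")
  start <- annotate_coding_snv(cds, 2, "T", "C") # ATG -> ACG start lost
  expect_equal(start$category, "start_lost")
})

test_that("annotator input contracts are enforced", {
  cds <- "ATGCTGTGGTAA"
  expect_error(annotate_coding_snv("ATGC", 1, "A", "G"), "multiple of 3")
  expect_error(annotate_coding_snv("TTGCTGTGGTAA", 1, "T", "A"),
               "start with ATG")
  expect_error(annotate_coding_snv(cds, 99, "A", "G"), "outside CDS")
  expect_error(annotate_coding_snv(cds, 6, "C", "A"),
               "expected C, found G")
  expect_error(annotate_coding_snv(cds, 6, "G", "G"), "must differ")
})

test_that("the built-in genetic code matches Biostrings", {
  skip_if_not_installed("Biostrings")
  ref <- Biostrings::GENETIC_CODE
  mine <- pik3r1iso:::GENETIC_CODE_DNA
  # Biostrings keys are RNA-less DNA codons too; align names
  expect_equal(mine[sort(names(mine))],
               ref[sort(names(mine))])
})

test_that("annotation agrees with a whole-CDS retranslation oracle", {
  skip_if_not_installed("Biostrings")
  translate_full <- function(cds) {
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       no.init.codon = TRUE))
  }
  set.seed(53)
  for (i in 1:1000) {
    cds <- random_cds(sample(4:12, 1))
    pos <- sample(nchar(cds), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ann <- annotate_coding_snv(cds, pos, ref, alt)
    mut <- cds
    substr(mut, pos, pos) <- alt
    p_ref <- translate_full(cds)
    p_alt <- translate_full(mut)
    if (p_ref == p_alt) {
      expect_equal(ann$category, "synonymous")
    } else {
      diff_at <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
      expect_equal(ann$codon_index, diff_at)
      expect_equal(ann$ref_aa, substr(p_ref, diff_at, diff_at))
      expect_equal(ann$alt_aa, substr(p_alt, diff_at, diff_at))
      if (diff_at == 1) {
        expect_equal(ann$category, "start_lost")
      } else if (substr(p_alt, diff_at, diff_at) == "*") {
        expect_equal(ann$category, "stop_gained")
      } else {
        expect_equal(ann$category, "missense")
      }
    }
  }
})
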