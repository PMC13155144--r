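test_that("junction strings parse with dash/comma tolerance and swap warning", {
  j <- parse_junction_region("chr5:68281007-68292258:+")
  expect_equal(unclass(j)[c("chrom", "start", "end", "strand")],
               list(chrom = "chr5", start = 68281007, end = 68292258,
                    strand = "+"))
  # en-dash separator as printed in publications
  j2 <- parse_junction_region("chr5:68281007–68292258:+")
  expect_equal(format(j2), format(j))
  j3 <- parse_junction_region("chr1:100-200:-")
  expect_equal(format(j3), "chr1:100-200:-")
  # reversed interval with grouping commas: swapped with a warning
  expect_warning(j4 <- parse_junction_region("5:68,290,834-68,281,006:+"),
                 "start > end")
  expect_equal(unclass(j4)[c("start", "end")],
               list(start = 68281006, end = 68290834))
})

test_that("malformed junction strings raise parse errors naming the token", {
  expect_error(parse_junction_region("chr5:abc-200:+"), "abc")
  expect_error(parse_junction_region("chr5:100-200:?"), "\\?")
  expect_error(parse_junction_region("no-colons-here"), "malformed")
  expect_error(parse_junction_region("chr1:100-100:+"), "start == end")
})

test_that("parser round trip: format then reparse is identity", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample.int(1e8, 2)
    j <- genomic_junction(paste0("chr", sample(1:22, 1)), min(a), max(a) + 1,
                          sample(c("+", "-"), 1))
    expect_equal(parse_junction_region(format(j)), j)
  }
})

test_that("junction TSV round trip preserves shape and exact counts", {
  jm <- make_test_jm(counts85 = c(12, 3), counts55 = c(0, 7),
                     samples = c("A-1", "B-2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_junction_tsv(jm, path)
  jm2 <- read_junction_matrix(path, format = "tsv")
  expect_equal(jm2$counts, jm$counts)
  expect_equal(jm2$junctions, jm$junctions)
})

test_that("STAR splice-junction files merge with missing-junction zeros", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "s1.tab"); f2 <- file.path(d, "s2.tab")
  # chrom start end strand-code motif annotated unique multi overhang
  writeLines(c("chr5\t100\t200\t1\t1\t1\t12\t3\t20",
               "chr5\t300\t400\t2\t2\t0\t5\t0\t18"), f1)
  writeLines("chr5\t100\t200\t1\t1\t1\t8\t1\t25", f2)
  jm <- read_junction_matrix(c(s1 = f1, s2 = f2), format = "star_sj")
  expect_equal(dim(jm$counts), c(2L, 2L))
  expect_equal(unname(jm$counts["chr5:100-200:+", ]), c(12, 8))
  expect_equal(unname(jm$counts["chr5:300-400:-", ]), c(5, 0))
  # the multi-mapper column is included on request
  jt <- read_junction_matrix(c(s1 = f1, s2 = f2), format = "star_sj",
                             count_column = "total")
  expect_equal(unname(jt$counts["chr5:100-200:+", ]), c(15, 9))
})

test_that("corrupt junction files are format errors", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tab")
  writeLines("chr5\t100\t200\t1\t1\t1\t-1\t0\t20", f)
  expect_error(read_junction_matrix(f, format = "star_sj"), "negative")
  writeLines(c("chr5\t100\t200\t1\t1\t1\t4\t0\t20",
               "chr5\t100\t200\t1\t1\t1\t6\t0\t20"), f)
  expect_error(read_junction_matrix(f, format = "star_sj"), "duplicate")
  writeLines("chr5\t100\t200\t0\t1\t1\t4\t0\t20", f)
  expect_error(read_junction_matrix(f, format = "star_sj"), "strand")
  ftsv <- file.path(d, "bad.tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tS1", "chr5\t100\t200\t+\t-1"),
             ftsv)
  expect_error(read_junction_matrix(ftsv, format = "tsv"), "negative")
  writeLines(c("chr\tbegin\tstop\tstrand\tS1", "chr5\t100\t200\t+\t1"),
             ftsv)
  expect_error(read_junction_matrix(ftsv, format = "tsv"), "header")
})

test_that("isoform quantification sums exactly matching junctions", {
  jm <- make_test_jm(counts85 = c(12, 0), counts55 = c(0, 7))
  et <- quantify_isoforms(jm, pik3r1_isoforms())
  expect_equal(et$p85a_raw, c(12, 0))
  expect_equal(et$p55a_raw, c(0, 7))
  expect_equal(et$p85a_log, log10(c(13, 1)))
  expect_equal(et$p55a_log, log10(c(1, 8)))
})

test_that("strand must match and absent junctions contribute zero", {
  jm <- make_test_jm()   # contains a minus-strand decoy with count 99
  defs <- list(isoform_definition("minus", "G",
                 genomic_junction("chr5", 68281007, 68292258, "-")),
               isoform_definition("absent", "G",
                 genomic_junction("chr9", 1000, 2000, "+")))
  et <- quantify_isoforms(jm, defs)
  expect_equal(et$minus_raw, c(99, 99))   # matches the decoy, not p85a
  expect_equal(et$absent_raw, c(0, 0))
  expect_equal(et$absent_log, c(0, 0))    # log10(0 + 1) == 0
})

test_that("quantification is additive and order-invariant", {
  set.seed(5)
  n_j <- 6; n_s <- 4
  jdf <- data.frame(chrom = "chr1", start = 100 * seq_len(n_j),
                    end = 100 * seq_len(n_j) + 50, strand = "+")
  cnt <- matrix(rpois(n_j * n_s, 20), n_j, n_s)
  jm <- junction_matrix(jdf, cnt, paste0("S", 1:n_s))
  js <- lapply(1:2, function(i)
    genomic_junction("chr1", 100 * i, 100 * i + 50, "+"))
  both <- quantify_isoforms(jm, list(
    isoform_definition("ab", "G", js)))
  one <- quantify_isoforms(jm, list(isoform_definition("a", "G", js[1])))
  two <- quantify_isoforms(jm, list(isoform_definition("b", "G", js[2])))
  # additivity against the per-junction sum
  expect_equal(both$ab_raw, one$a_raw + two$b_raw)
  # permuting rows and columns of the input never changes the output
  perm_r <- sample(n_j); perm_c <- sample(n_s)
  jm2 <- junction_matrix(jdf[perm_r, ], cnt[perm_r, perm_c],
                         paste0("S", 1:n_s)[perm_c])
  both2 <- quantify_isoforms(jm2, list(isoform_definition("ab", "G", js)))
  expect_equal(both2$ab_raw[match(both$sample_barcode,
                                  both2$sample_barcode)],
               both$ab_raw)
})

test_that("definition errors are caught", {
  jm <- make_test_jm()
  expect_error(quantify_isoforms(jm, list()), "at least one")
  j <- genomic_junction("chr5", 68281007, 68292258, "+")
  dup <- list(isoform_definition("x", "PIK3R1", j),
              isoform_definition("y", "PIK3R1", j))
  expect_error(quantify_isoforms(jm, dup), "two isoform definitions")
  expect_error(quantify_isoforms(jm, pik3r1_isoforms(), pseudocount = 0),
               "positive")
})

test_that("log transform is zero iff raw is zero and strictly increasing", {
  raw <- 0:50
  lg <- log10(raw + 1)
  expect_true(all((lg == 0) == (raw == 0)))
  expect_true(all(diff(lg) > 0))
})

test_that("expression CSV round trips", {
  jm <- make_test_jm(counts85 = c(12, 5), counts55 = c(1, 7))
  et <- quantify_isoforms(jm, pik3r1_isoforms(),
                          sample_type = c(S1 = "tumor", S2 = "normal"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_csv(et, path)
  expect_equal(length(readLines(path)), nrow(et) + 1L)
  back <- read_expression_csv(path)
  expect_equal(back$p85a_raw, et$p85a_raw)
  expect_equal(back$sample_type, et$sample_type)
  expect_equal(back$p85a_log, et$p85a_log, tolerance = 1e-12)
  empty <- et[0, ]
  expect_error(write_expression_csv(empty, path), "non-empty")
})
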