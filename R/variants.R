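#' Variant region classification, consequence tallies, coding-SNV annotation
#'
#' Variants are classified into the isoform-specific genomic regions of
#' PIK3R1 (closed-interval containment), consequence classes are tallied
#' per region in the shape of a variants-by-region summary table, shared
#' variants (inside both regions) are identified, and coding SNVs are
#' annotated at codon level with HGVS p. nomenclature.
#'
#' @name variant_annot
NULL

#' The fixed consequence-class vocabulary
#' @return Character vector of recognized consequence classes.
#' @export
consequence_classes <- function() {
  c("5_prime_UTR", "3_prime_UTR", "intron", "splice_region", "splice_donor",
    "splice_acceptor", "missense", "start_lost", "start_gained",
    "stop_gained", "frameshift", "synonymous", "inframe_insertion", "other")
}

# map free-text annotation strings (gnomAD/VEP style) onto the vocabulary
normalize_consequence <- function(x) {
  key <- tolower(gsub("[ '′‐-]", "_", trimws(as.character(x))))
  key <- gsub("_+", "_", key)
  key <- sub("_variant$", "", key)
  map <- c("5_utr" = "5_prime_UTR", "5_prime_utr" = "5_prime_UTR",
           "3_utr" = "3_prime_UTR", "3_prime_utr" = "3_prime_UTR",
           "intron" = "intron", "intronic" = "intron",
           "splice_region" = "splice_region",
           "splice_donor" = "splice_donor",
           "splice_acceptor" = "splice_acceptor",
           "missense" = "missense",
           "start_lost" = "start_lost", "start_gained" = "start_gained",
           "stop_gained" = "stop_gained", "stop" = "stop_gained",
           "frameshift" = "frameshift",
           "synonymous" = "synonymous",
           "inframe_insertion" = "inframe_insertion",
           "in_frame_insertion" = "inframe_insertion")
  vocab <- consequence_classes()
  out <- ifelse(key %in% tolower(vocab),
                vocab[match(key, tolower(vocab))],
                unname(map[key]))
  unknown <- is.na(out) & !is.na(x) & nzchar(trimws(as.character(x)))
  if (any(unknown))
    warning("unknown consequence string(s) mapped to 'other': ",
            paste(unique(x[unknown]), collapse = ", "))
  out[is.na(out)] <- "other"
  out
}

validate_variants <- function(df, source = "input") {
  if (any(df$pos < 1))
    stop("variant position < 1 at row ", which(df$pos < 1)[1], " of ", source)
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    stop("empty allele at row ",
         which(!nzchar(df$ref) | !nzchar(df$alt))[1], " of ", source)
  same <- df$ref == df$alt
  if (any(same))
    stop("ref == alt at row ", which(same)[1], " of ", source)
  df
}

#' Read variant records
#'
#' VCF 4.x (the 8 mandatory columns; multi-allelic rows are split into one
#' record per alternate allele) or a tab-separated export with header
#' columns `chrom`, `pos`, `ref`, `alt` and optionally `rsid` and
#' `consequence`. Consequence strings outside the fixed vocabulary are
#' mapped to `"other"` with a warning.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param consequence_info_key For VCF input, the INFO key holding the
#'   consequence class (default `"CSQ"`; absent key gives `"other"`).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `rsid`,
#'   `consequence`.
#' @export
read_variants <- function(path, format = c("tsv", "vcf"),
                          consequence_info_key = "CSQ") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("variant TSV needs columns ", paste(need, collapse = ", "))
    pos <- suppressWarnings(as.numeric(df$pos))
    if (any(is.na(pos)))
      stop("non-numeric position at row ", which(is.na(pos))[1],
           " of '", path, "'")
    out <- data.frame(chrom = df$chrom, pos = pos, ref = toupper(df$ref),
                      alt = toupper(df$alt),
                      rsid = if ("rsid" %in% names(df)) df$rsid
                             else NA_character_,
                      consequence = if ("consequence" %in% names(df))
                        normalize_consequence(df$consequence)
                        else "other",
                      stringsAsFactors = FALSE)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                         stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) stop("no variant rows in '", path, "'")
    csq <- rep(NA_character_, nrow(fix))
    if (!is.null(fix$INFO)) {
      pat <- paste0("(?:^|;)", consequence_info_key, "=([^;]+)")
      m <- regmatches(fix$INFO, regexec(pat, fix$INFO))
      csq <- vapply(m, function(x) if (length(x) == 2L) x[2]
                    else NA_character_, "")
    }
    rows <- lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      data.frame(chrom = fix$CHROM[i],
                 pos = as.numeric(fix$POS[i]),
                 ref = toupper(fix$REF[i]), alt = toupper(alts),
                 rsid = ifelse(fix$ID[i] %in% c(".", ""), NA_character_,
                               fix$ID[i]),
                 consequence = csq[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$consequence <- ifelse(is.na(out$consequence), "other",
                              normalize_consequence(out$consequence))
  }
  validate_variants(out, source = path)
}

#' Define a named genomic region (closed interval)
#'
#' Reversed bounds (start > end), as printed for minus-strand transcripts
#' reported 5'->3', are normalized by swapping.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval bounds.
#' @return A `genomic_region` list.
#' @export
genomic_region <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) { tmp <- start; start <- end; end <- tmp }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' The PIK3R1 isoform-specific variant regions (GRCh38)
#'
#' The published region coordinates: 5:68,290,834-68,281,006 for p85a
#' (printed 5'->3'; normalized to genomic order) and 5:68,290,834-68,292,259
#' for p55a. The two closed intervals meet at 68,290,834.
#'
#' @return Named list of two [genomic_region()]s, `p85a` and `p55a`.
#' @export
pik3r1_regions <- function() {
  list(p85a = genomic_region("5", 68290834, 68281006),
       p55a = genomic_region("5", 68290834, 68292259))
}

#' Classify variants into isoform regions
#'
#' Closed-interval containment on both bounds: inside both regions gives
#' `"shared"`, inside exactly one gives that region, otherwise
#' `"outside"`. A chromosome mismatch classifies as outside with a
#' warning.
#'
#' @param variants Data frame with `chrom` and `pos` columns (or a single
#'   position via `chrom=`, `pos=`).
#' @param regions A two-region list as from [pik3r1_regions()]; names must
#'   be the region labels.
#' @return Character vector over `{"<region1>_only", "<region2>_only",
#'   "shared", "outside"}`.
#' @export
classify_region <- function(variants, regions = pik3r1_regions()) {
  stopifnot(length(regions) == 2L, !is.null(names(regions)))
  r1 <- regions[[1]]; r2 <- regions[[2]]
  chrom <- as.character(variants$chrom)
  pos <- variants$pos
  mismatch <- chrom != r1$chrom & chrom != r2$chrom
  if (any(mismatch))
    warning(sum(mismatch), " variant(s) on other chromosome(s); ",
            "classified as outside")
  in1 <- chrom == r1$chrom & pos >= r1$start & pos <= r1$end
  in2 <- chrom == r2$chrom & pos >= r2$start & pos <= r2$end
  ifelse(in1 & in2, "shared",
    ifelse(in1, paste0(names(regions)[1], "_only"),
      ifelse(in2, paste0(names(regions)[2], "_only"), "outside")))
}

#' Tally variant consequences per isoform region
#'
#' Counts of each consequence class per region (a shared variant counts in
#' both regions, as in a per-isoform variant summary table), the rsIDs
#' present in both regions, and per-region totals.
#'
#' @param variants Data frame with `chrom`, `pos`, `consequence` and
#'   optionally `rsid`.
#' @param regions As for [classify_region()].
#' @return A `consequence_tally`: list with `counts` (class x region
#'   matrix), `totals`, `shared` (rsIDs), `membership`.
#' @export
tally_consequences <- function(variants, regions = pik3r1_regions()) {
  classes <- consequence_classes()
  rnames <- names(regions)
  if (nrow(variants) == 0L) {
    counts <- matrix(0L, length(classes), 2,
                     dimnames = list(classes, rnames))
    return(structure(list(counts = counts,
                          totals = stats::setNames(c(0L, 0L), rnames),
                          shared = character(0),
                          membership = character(0)),
                     class = "consequence_tally"))
  }
  member <- classify_region(variants, regions)
  csq <- factor(variants$consequence, levels = classes)
  if (anyNA(csq)) stop("consequence outside the fixed vocabulary")
  in1 <- member %in% c(paste0(rnames[1], "_only"), "shared")
  in2 <- member %in% c(paste0(rnames[2], "_only"), "shared")
  counts <- cbind(table(csq[in1]), table(csq[in2]))
  dimnames(counts) <- list(classes, rnames)
  shared <- if ("rsid" %in% names(variants))
    unique(variants$rsid[member == "shared" & !is.na(variants$rsid)])
    else character(0)
  structure(list(counts = counts,
                 totals = stats::setNames(colSums(counts), rnames),
                 shared = shared, membership = member),
            class = "consequence_tally")
}

#' @export
print.consequence_tally <- function(x, ...) {
  cat("<consequence_tally> totals:",
      paste(names(x$totals), x$totals, sep = " = ", collapse = ", "),
      "; shared rsIDs:", length(x$shared), "\n")
  print(x$counts[rowSums(x$counts) > 0, , drop = FALSE])
  invisible(x)
}

#' Write a consequence tally as CSV
#'
#' @param tally A `consequence_tally`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path) {
  df <- data.frame(consequence = c(rownames(tally$counts), "total"),
                   rbind(tally$counts, tally$totals),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# standard genetic code, DNA codons -> one-letter amino acids ('*' = stop);
# checked against Biostrings::GENETIC_CODE in the test suite
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "Ter")

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_DNA[[toupper(codon)]]
  if (is.null(aa)) stop("not a DNA codon: '", codon, "'")
  aa
}

#' Annotate the protein consequence of a coding SNV
#'
#' Locates the codon containing the substituted coding position
#' (codon index = ceiling(pos / 3)), translates the reference and mutated
#' codon by the standard genetic code, and reports the HGVS p. string with
#' three-letter amino-acid codes plus a category: `synonymous`
#' (`"p.(=)"`), `missense`, `stop_gained` (`Ter`), or `start_lost` (a
#' non-synonymous change in codon 1).
#'
#' @param cds Coding sequence (string over ACGT), length a multiple of 3,
#'   starting with ATG.
#' @param coding_pos 1-based position within the CDS (c. coordinate).
#' @param ref,alt Single reference and alternate nucleotides; `ref` must
#'   match the CDS at `coding_pos`.
#' @return A list: `hgvs_p`, `category`, `codon_index`, `ref_aa`, `alt_aa`
#'   (one-letter).
#' @export
annotate_coding_snv <- function(cds, coding_pos, ref, alt) {
  cds <- toupper(gsub("[[:space:]]", "", cds))
  if (!grepl("^[ACGT]+$", cds)) stop("`cds` must be a DNA string over ACGT")
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must start with ATG")
  if (coding_pos < 1 || coding_pos > nchar(cds))
    stop("coding position ", coding_pos, " outside CDS of length ",
         nchar(cds))
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stop("`ref` and `alt` must be single nucleotides")
  if (ref == alt) stop("`ref` and `alt` must differ")
  found <- substr(cds, coding_pos, coding_pos)
  if (found != ref)
    stop("reference mismatch at coding position ", coding_pos,
         ": expected ", ref, ", found ", found)
  ci <- ceiling(coding_pos / 3)
  codon <- substr(cds, 3 * ci - 2, 3 * ci)
  within <- coding_pos - (3 * ci - 3)
  mut <- codon
  substr(mut, within, within) <- alt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(mut)
  if (aa_ref == aa_alt) {
    category <- "synonymous"
    hgvs <- "p.(=)"
  } else if (ci == 1L) {
    category <- "start_lost"
    hgvs <- "p.Met1?"
  } else if (aa_alt == "*") {
    category <- "stop_gained"
    hgvs <- sprintf("p.%s%dTer", AA_THREE[[aa_ref]], ci)
  } else {
    category <- "missense"
    hgvs <- sprintf("p.%s%d%s", AA_THREE[[aa_ref]], ci, AA_THREE[[aa_alt]])
  }
  list(hgvs_p = hgvs, category = category, codon_index = ci,
       ref_aa = aa_ref, alt_aa = aa_alt)
}
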