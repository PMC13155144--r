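#' Genomic splice junctions and junction count matrices
#'
#' A splice junction is identified by the intron it evidences: chromosome,
#' first and last intronic base (1-based, fully closed, recount3-style) and
#' strand. Junction read counts at isoform-discriminating junctions measure
#' the expression of individual alternative-first-exon isoforms.
#'
#' @name junctions
NULL

#' Construct a genomic junction
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 1-based position of the first intronic base.
#' @param end 1-based position of the last intronic base; must exceed `start`.
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_junction` object (named list).
#' @export
genomic_junction <- function(chrom, start, end, strand) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("`chrom` must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 1 || end < 1 ||
      start != trunc(start) || end != trunc(end))
    stop("`start` and `end` must be positive integers")
  if (!(strand %in% c("+", "-")))
    stop("`strand` must be '+' or '-', got '", strand, "'")
  if (start >= end)
    stop("invalid interval: start (", start, ") must be < end (", end, ")")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_junction")
}

#' @export
format.genomic_junction <- function(x, ...) {
  sprintf("%s:%d-%d:%s", x$chrom, x$start, x$end, x$strand)
}

#' @export
print.genomic_junction <- function(x, ...) {
  cat("<junction>", format(x), "\n")
  invisible(x)
}

junction_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse a junction region string
#'
#' Accepts the `chrom:start-end:strand` notation used in genome browsers and
#' publications. The position separator may be an ASCII hyphen or any common
#' Unicode dash; digit-grouping commas are stripped. Intervals printed in
#' reversed order (start > end), as happens for minus-strand genes reported
#' 5'->3' of the transcript, are normalized by swapping with a warning.
#'
#' @param text A single string such as `"chr5:68281007-68292258:+"`.
#' @return A [genomic_junction()].
#' @examples
#' parse_junction_region("chr5:68281007-68292258:+")
#' @export
parse_junction_region <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single string")
  s <- gsub(",", "", trimws(text), fixed = TRUE)
  # unify unicode hyphen/dash/minus variants to ASCII
  s <- gsub("[‐‑‒–—―−]", "-", s)
  m <- regmatches(s, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+):([+-])$", s))[[1]]
  if (length(m) == 0L) {
    # identify the offending token for the error message
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    bad <- if (length(parts) != 3L) s else {
      rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
      if (length(rng) != 2L || !all(grepl("^[0-9]+$", rng))) parts[2]
      else if (!parts[3] %in% c("+", "-")) parts[3]
      else parts[1]
    }
    stop("malformed junction string '", text, "': cannot parse token '", bad, "'")
  }
  chrom <- m[2]; start <- as.numeric(m[3]); end <- as.numeric(m[4]); strand <- m[5]
  if (start == end)
    stop("invalid interval in '", text, "': start == end")
  if (start > end) {
    warning("junction '", text, "' has start > end; swapping to genomic order")
    tmp <- start; start <- end; end <- tmp
  }
  genomic_junction(chrom, start, end, strand)
}

#' Construct a junction count matrix
#'
#' @param junctions A data frame with columns `chrom`, `start`, `end`,
#'   `strand`, one row per junction.
#' @param counts Non-negative integer matrix, junctions x samples.
#' @param samples Character vector of sample barcodes (column order of
#'   `counts`).
#' @return A `junction_matrix` object.
#' @export
junction_matrix <- function(junctions, counts, samples) {
  junctions <- as.data.frame(junctions)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(junctions)))
    stop("`junctions` must have columns ", paste(need, collapse = ", "))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(junctions) || ncol(counts) != length(samples))
    stop("`counts` dimensions (", nrow(counts), "x", ncol(counts),
         ") do not match ", nrow(junctions), " junctions x ",
         length(samples), " samples")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts must be finite and >= 0")
  keys <- junction_key(junctions$chrom, junctions$start, junctions$end,
                       junctions$strand)
  if (anyDuplicated(keys))
    stop("duplicate junction key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample barcode(s)")
  # deterministic ordering: chrom, start, end, strand
  ord <- order(junctions$chrom, junctions$start, junctions$end,
               junctions$strand)
  junctions <- junctions[ord, need, drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(junctions) <- NULL
  dimnames(counts) <- list(keys[ord], samples)
  structure(list(junctions = junctions, counts = counts,
                 samples = as.character(samples)),
            class = "junction_matrix")
}

#' @export
print.junction_matrix <- function(x, ...) {
  cat("<junction_matrix> ", nrow(x$counts), " junctions x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Read a junction count matrix
#'
#' Two on-disk layouts are supported: a single TSV with one header row of
#' sample barcodes and one row per junction keyed by
#' `chrom`/`start`/`end`/`strand`, or a set of per-sample splice-junction
#' files in the 9-column STAR `SJ.out.tab` format (one file per sample,
#' merged on the junction key; a junction absent from a sample contributes a
#' count of 0).
#'
#' @param path File path (TSV) or character vector of per-sample file paths
#'   (STAR format). For STAR files, names of `path` give the sample
#'   barcodes; unnamed paths use the file base name.
#' @param format `"tsv"` or `"star_sj"`.
#' @param count_column For STAR files, `"unique"` (column 7, uniquely
#'   mapping reads; the default) or `"total"` (unique + multi-mapping).
#' @return A [junction_matrix()].
#' @export
read_junction_matrix <- function(path, format = c("tsv", "star_sj"),
                                 count_column = c("unique", "total")) {
  format <- match.arg(format)
  count_column <- match.arg(count_column)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand")
    if (!all(need %in% names(df)[seq_len(4)]))
      stop("inconsistent header in '", path, "': expected columns ",
           paste(need, collapse = ", "), " then sample barcodes")
    samples <- names(df)[-seq_len(4)]
    if (length(samples) == 0L) stop("no sample columns in '", path, "'")
    cnt <- as.matrix(df[, -seq_len(4), drop = FALSE])
    bad <- which(!is.finite(cnt) | cnt < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("negative or non-numeric count at row ", bad[1, 1],
           " of '", path, "'")
    junction_matrix(df[, need], cnt, samples)
  } else {
    files <- path
    barcodes <- names(files)
    if (is.null(barcodes) || any(!nzchar(barcodes)))
      barcodes <- sub("\\.[^.]*$", "", basename(files))
    per <- lapply(seq_along(files), function(i) {
      sj <- utils::read.table(files[i], header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)
      if (ncol(sj) != 9L)
        stop("'", files[i], "' is not 9-column splice-junction format")
      strand_code <- sj[[4]]
      if (any(strand_code == 0L))
        stop("undefined strand (code 0) at row ", which(strand_code == 0L)[1],
             " of '", files[i], "'")
      cnt <- sj[[7]] + if (count_column == "total") sj[[8]] else 0L
      if (any(cnt < 0))
        stop("negative count at row ", which(cnt < 0)[1], " of '", files[i], "'")
      key <- junction_key(sj[[1]], sj[[2]], sj[[3]],
                          c("+", "-")[strand_code])
      if (anyDuplicated(key))
        stop("duplicate junction key at row ", which(duplicated(key))[1],
             " of '", files[i], "'")
      data.frame(chrom = sj[[1]], start = sj[[2]], end = sj[[3]],
                 strand = c("+", "-")[strand_code], key = key,
                 count = cnt, stringsAsFactors = FALSE)
    })
    all_j <- unique(do.call(rbind, lapply(per, function(d)
      d[c("chrom", "start", "end", "strand", "key")])))
    cnt <- matrix(0, nrow = nrow(all_j), ncol = length(files),
                  dimnames = list(all_j$key, barcodes))
    for (i in seq_along(per))
      cnt[per[[i]]$key, i] <- per[[i]]$count
    junction_matrix(all_j[c("chrom", "start", "end", "strand")], cnt, barcodes)
  }
}

#' Define an isoform by its discriminating junction(s)
#'
#' @param name Isoform label, e.g. `"p85a"`.
#' @param gene Gene symbol.
#' @param junctions A list of [genomic_junction()]s unique to this isoform
#'   (at least one).
#' @return An `isoform_definition` object.
#' @export
isoform_definition <- function(name, gene, junctions) {
  if (inherits(junctions, "genomic_junction")) junctions <- list(junctions)
  if (length(junctions) == 0L)
    stop("an isoform definition needs at least one junction")
  stopifnot(all(vapply(junctions, inherits, TRUE, "genomic_junction")))
  structure(list(name = name, gene = gene, junctions = junctions),
            class = "isoform_definition")
}

#' The PIK3R1 isoform definitions used throughout the package
#'
#' p85a, the full-length regulatory isoform, is identified by the junction
#' whose excised intron spans chr5:68281007-68292258 (+); the shorter
#' alternative-first-exon isoform p55a by chr5:68290835-68292258 (+). The
#' two junctions share their acceptor coordinate (hg38).
#'
#' @return A list of two [isoform_definition()]s named `p85a` and `p55a`.
#' @export
pik3r1_isoforms <- function() {
  list(
    p85a = isoform_definition("p85a", "PIK3R1",
      parse_junction_region("chr5:68281007-68292258:+")),
    p55a = isoform_definition("p55a", "PIK3R1",
      parse_junction_region("chr5:68290835-68292258:+"))
  )
}

#' Quantify isoform expression from junction counts
#'
#' For each isoform the raw expression of a sample is the sum of read counts
#' over junction rows whose (chrom, start, end, strand) exactly equal one of
#' the isoform's discriminating junctions; strand must match for a junction
#' to count, and a discriminating junction absent from the matrix
#' contributes 0. Log expression is `log10(raw + pseudocount)`.
#'
#' @param jm A [junction_matrix()].
#' @param defs A list of [isoform_definition()]s.
#' @param pseudocount Positive number added before the log10 transform
#'   (default 1, so a raw count of 0 maps to log expression 0).
#' @param sample_type Optional character vector (named by barcode, or in
#'   sample order) of `"tumor"`/`"normal"` labels carried into the table.
#' @return A data frame of class `expression_table` with columns
#'   `sample_barcode`, `sample_type`, and `<isoform>_raw`, `<isoform>_log`
#'   per isoform.
#' @export
quantify_isoforms <- function(jm, defs, pseudocount = 1, sample_type = NULL) {
  stopifnot(inherits(jm, "junction_matrix"))
  if (length(defs) == 0L) stop("`defs` must contain at least one isoform definition")
  stopifnot(all(vapply(defs, inherits, TRUE, "isoform_definition")))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("`pseudocount` must be a single positive number")
  # within one gene no junction may discriminate two isoforms
  all_keys <- lapply(defs, function(d)
    vapply(d$junctions, function(j) format(j), ""))
  genes <- vapply(defs, `[[`, "", "gene")
  for (g in unique(genes)) {
    kg <- unlist(all_keys[genes == g])
    if (anyDuplicated(kg))
      stop("junction ", kg[duplicated(kg)][1],
           " appears in two isoform definitions of gene ", g)
  }
  if (is.null(sample_type)) {
    sample_type <- rep(NA_character_, length(jm$samples))
  } else if (!is.null(names(sample_type))) {
    sample_type <- unname(sample_type[jm$samples])
  }
  et <- data.frame(sample_barcode = jm$samples,
                   sample_type = sample_type,
                   stringsAsFactors = FALSE)
  row_keys <- rownames(jm$counts)
  for (d in defs) {
    keys <- vapply(d$junctions, function(j) format(j), "")
    hit <- row_keys %in% keys
    raw <- if (any(hit)) colSums(jm$counts[hit, , drop = FALSE]) else
      stats::setNames(rep(0, length(jm$samples)), jm$samples)
    et[[paste0(d$name, "_raw")]] <- unname(raw)
    et[[paste0(d$name, "_log")]] <- log10(unname(raw) + pseudocount)
  }
  attr(et, "pseudocount") <- pseudocount
  attr(et, "isoforms") <- vapply(defs, `[[`, "", "name")
  class(et) <- c("expression_table", "data.frame")
  et
}

#' Write / read a per-sample isoform expression table
#'
#' The CSV carries one row per sample with columns `sample_barcode`,
#' `sample_type` and the `<isoform>_raw` / `<isoform>_log` pairs. Reading a
#' written file reproduces raw counts bit-exactly and log values to at
#' least 12 decimal places.
#'
#' @param et An `expression_table` from [quantify_isoforms()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(et, path) {
  if (!is.data.frame(et) || nrow(et) == 0L)
    stop("`et` must be a non-empty expression table")
  utils::write.csv(as.data.frame(et), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  iso <- sub("_raw$", "", grep("_raw$", names(df), value = TRUE))
  attr(df, "isoforms") <- iso
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Write a junction matrix as TSV
#'
#' @param jm A [junction_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(jm, path) {
  stopifnot(inherits(jm, "junction_matrix"))
  df <- cbind(jm$junctions,
              as.data.frame(jm$counts, check.names = FALSE))
  names(df) <- c("chrom", "start", "end", "strand", jm$samples)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
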