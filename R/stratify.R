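#' Expression-group stratification and cohort construction
#'
#' Tumor samples are assigned to 'low'/'high' expression groups by one of
#' two rules: a mean split on log expression (used for the abundant p85a
#' isoform) or a zero/non-zero split on raw counts (used for p55a, whose
#' counts show a point mass at zero). Cohorts cross the expression groups
#' with cancer type, race and tumor/normal status.
#'
#' @name stratification
NULL

#' Split samples at the mean of their expression values
#'
#' The threshold is the arithmetic mean of the input values; a sample is
#' 'high' iff its value is strictly greater than the threshold, otherwise
#' 'low' (ties at exactly the mean are 'low'). Intended to be applied to
#' log-scale expression of one cancer type's tumor samples.
#'
#' @param values Numeric vector of per-sample expression (finite).
#' @param barcodes Sample barcodes; defaults to `names(values)`.
#' @return A data frame (class `group_labels`) with columns `barcode`,
#'   `rule`, `label`, `threshold_used`.
#' @export
split_by_mean <- function(values, barcodes = names(values)) {
  if (length(values) < 2L)
    stop("mean split needs at least 2 samples")
  if (any(!is.finite(values)))
    stop("non-finite expression value at position ",
         which(!is.finite(values))[1])
  if (is.null(barcodes)) barcodes <- paste0("S", seq_along(values))
  thr <- mean(values)
  lab <- ifelse(values > thr, "high", "low")
  if (all(values == values[1])) {
    warning("all expression values equal; every sample labeled 'low'")
    lab <- rep("low", length(values))
  }
  structure(data.frame(barcode = as.character(barcodes),
                       rule = "mean_split", label = lab,
                       threshold_used = thr, stringsAsFactors = FALSE),
            class = c("group_labels", "data.frame"))
}

#' Split samples into zero / non-zero expression groups
#'
#' A sample is 'low' iff its raw count equals 0 and 'high' otherwise
#' (threshold recorded as 0). This is the stratification rule for an
#' isoform whose count distribution carries a point mass at zero.
#'
#' @param raw_counts Integer vector of per-sample raw counts (>= 0).
#' @param barcodes Sample barcodes; defaults to `names(raw_counts)`.
#' @return A data frame (class `group_labels`) with columns `barcode`,
#'   `rule`, `label`, `threshold_used`.
#' @export
split_zero_nonzero <- function(raw_counts, barcodes = names(raw_counts)) {
  if (length(raw_counts) == 0L) stop("no samples supplied")
  if (any(!is.finite(raw_counts) | raw_counts < 0))
    stop("raw counts must be finite and >= 0; offending position ",
         which(!is.finite(raw_counts) | raw_counts < 0)[1])
  if (is.null(barcodes)) barcodes <- paste0("S", seq_along(raw_counts))
  structure(data.frame(barcode = as.character(barcodes),
                       rule = "zero_nonzero",
                       label = ifelse(raw_counts == 0, "low", "high"),
                       threshold_used = 0, stringsAsFactors = FALSE),
            class = c("group_labels", "data.frame"))
}

#' Normalize self-reported race strings to analysis groups
#'
#' Matches case-insensitively against a synonym table; anything not mapping
#' to AA (African American) or EA (European American) becomes `"NA-other"`,
#' which downstream group tests exclude (cohorts retain these samples).
#'
#' @param race Character vector of race strings as recorded in clinical
#'   metadata.
#' @param synonyms Named character vector mapping lower-case race strings to
#'   `"AA"` or `"EA"`; extendable by the caller.
#' @return Character vector over `{"AA", "EA", "NA-other"}`.
#' @export
normalize_race <- function(race,
                           synonyms = c("black or african american" = "AA",
                                        "african american" = "AA",
                                        "black" = "AA",
                                        "aa" = "AA",
                                        "white" = "EA",
                                        "european american" = "EA",
                                        "caucasian" = "EA",
                                        "ea" = "EA")) {
  key <- tolower(trimws(as.character(race)))
  out <- unname(synonyms[key])
  out[is.na(out)] <- "NA-other"
  out
}

#' Attach cohort keys (cancer, race, sample type) to labeled samples
#'
#' Partitions samples by (cancer type, race group, tumor/normal). Normal
#' samples carry no low/high label; samples whose race falls outside
#' AA/EA are retained under `"NA-other"` but flagged as excluded from group
#' tests.
#'
#' @param metadata Clinical data frame with at least `bcr_patient_barcode`,
#'   `type` (cancer code), `sample_type`, `race`.
#' @param labels A `group_labels` data frame ([split_by_mean()] /
#'   [split_zero_nonzero()]); every labeled barcode must appear in
#'   `metadata`.
#' @param race_synonyms Passed to [normalize_race()].
#' @return A data frame (class `cohort_assignments`) with one row per
#'   metadata sample: `barcode`, `cancer`, `race`, `sample_type`, `label`
#'   (NA for normals and unlabeled samples), `excluded_from_tests`.
#' @export
build_cohorts <- function(metadata, labels,
                          race_synonyms = NULL) {
  need <- c("bcr_patient_barcode", "type", "sample_type", "race")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  missing_bc <- setdiff(labels$barcode, metadata$bcr_patient_barcode)
  if (length(missing_bc) > 0L)
    stop("labeled barcode(s) missing from metadata: ",
         paste(missing_bc, collapse = ", "))
  race <- if (is.null(race_synonyms)) normalize_race(metadata$race)
          else normalize_race(metadata$race, race_synonyms)
  lab <- labels$label[match(metadata$bcr_patient_barcode, labels$barcode)]
  lab[metadata$sample_type != "tumor"] <- NA_character_
  structure(data.frame(
    barcode = metadata$bcr_patient_barcode,
    cancer = metadata$type,
    race = race,
    sample_type = metadata$sample_type,
    label = lab,
    excluded_from_tests = race == "NA-other",
    stringsAsFactors = FALSE
  ), class = c("cohort_assignments", "data.frame"))
}

#' Enumerate cohort cells
#'
#' @param cohorts A `cohort_assignments` data frame from [build_cohorts()].
#' @return A named list of barcode vectors, one element per occupied
#'   (cancer, race, sample_type) cell; names are `cancer.race.sample_type`.
#' @export
cohort_cells <- function(cohorts) {
  split(cohorts$barcode,
        interaction(cohorts$cancer, cohorts$race, cohorts$sample_type,
                    drop = TRUE))
}
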