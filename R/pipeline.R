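#' Pipeline orchestration
#'
#' Composes the stages into the full analysis flow: quantify isoform
#' expression, stratify per cancer type, tumor-vs-normal and race-group
#' tests, survival (log-rank and multivariate Cox for OS and PFI), protein
#' comparisons and variant tallies. Each cancer type runs independently;
#' a failure in one is logged and skipped, not fatal. Every output CSV
#' carries a provenance header comment (config hash and seed) and no
#' timestamps, so identical configurations give byte-identical outputs.
#'
#' @name pipeline
NULL

# small string hash for provenance (no cryptographic intent); path fields
# are excluded so that reruns in different directories hash identically
config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), c("junction_file", "clinical_file",
                                   "protein_file", "variant_file",
                                   "outdir"))]
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 17
  for (b in utf8ToInt(s))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pik3r1iso config_hash=%s seed=%s", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a pipeline configuration
#'
#' @param junction_file Junction TSV path (see [read_junction_matrix()]).
#' @param clinical_file Clinical metadata CSV path (TCGA-CDR-like schema).
#' @param protein_file,variant_file Optional protein CSV / variant TSV
#'   paths; omitted stages are reported as not run.
#' @param outdir Output directory for stage CSVs.
#' @param isoforms Isoform definitions (default [pik3r1_isoforms()]).
#' @param regions Variant regions (default [pik3r1_regions()]).
#' @param pseudocount Log-transform pseudocount.
#' @param exact_max_n Exact-Wilcoxon combined-n bound.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg across
#'   cancer types / proteins.
#' @param ties Cox tie method.
#' @param covariates Cox adjustment covariates (clinical column names).
#' @param seed Seed recorded in provenance and used for any resampling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(junction_file, clinical_file,
                            protein_file = NULL, variant_file = NULL,
                            outdir = tempfile("pik3r1iso_run_"),
                            isoforms = pik3r1_isoforms(),
                            regions = pik3r1_regions(),
                            pseudocount = 1, exact_max_n = 12L,
                            adjust = c("none", "BH"),
                            ties = c("efron", "breslow"),
                            covariates = c("age", "gender", "race",
                                           "stage", "smoking_history",
                                           "alcohol_history"),
                            seed = 1L) {
  adjust <- match.arg(adjust)
  ties <- match.arg(ties)
  for (f in c(junction_file, clinical_file, protein_file, variant_file))
    if (!is.null(f) && !file.exists(f))
      stop("config error: input file does not exist: ", f)
  structure(list(junction_file = junction_file,
                 clinical_file = clinical_file,
                 protein_file = protein_file, variant_file = variant_file,
                 outdir = outdir, isoforms = isoforms, regions = regions,
                 pseudocount = pseudocount,
                 exact_max_n = as.integer(exact_max_n),
                 adjust = adjust, ties = ties, covariates = covariates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be given in a YAML mapping;
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)),
                   c("isoforms", "regions"))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("config error: unknown key(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

# collapse AJCC stage strings to an early/advanced contrast
collapse_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  adv <- grepl("III|IV|3|4", s)
  early <- grepl("\\bI\\b|\\bII\\b|STAGE I$|STAGE II$|1|2", s) & !adv
  out <- rep(NA_character_, length(s))
  out[adv] <- "advanced"
  out[early] <- "early"
  out
}

survival_stage <- function(clin, labels, endpoint, cfg, iso_name) {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  lab <- labels$label[match(clin$bcr_patient_barcode, labels$barcode)]
  keep <- !is.na(clin[[tcol]]) & !is.na(clin[[ecol]]) & !is.na(lab)
  d <- clin[keep, , drop = FALSE]
  lab <- lab[keep]
  if (sum(d[[ecol]]) < 1 || length(unique(lab)) < 2)
    return(list(logrank = NULL, cox = NULL,
                note = "insufficient events or single group"))
  lr <- logrank_test(d[[tcol]], d[[ecol]], lab)
  cov <- data.frame(group = lab, stringsAsFactors = FALSE)
  for (cn in cfg$covariates) {
    v <- if (cn == "stage") collapse_stage(d$ajcc_stage)
         else if (cn == "race") normalize_race(d$race)
         else d[[cn]]
    cov[[cn]] <- v
  }
  mask <- stats::complete.cases(cov)
  if ("race" %in% names(cov))
    mask <- mask & cov$race != "NA-other"
  n_dropped <- sum(!mask)
  cov <- cov[mask, , drop = FALSE]
  fit <- tryCatch({
    # drop covariates that became constant after complete-case deletion
    keep_cols <- vapply(cov, function(v) length(unique(v)) > 1L, TRUE)
    cox_fit(d[[tcol]][mask], d[[ecol]][mask],
            cov[, keep_cols, drop = FALSE],
            ties = cfg$ties,
            reference = list(group = "high", stage = "early"))
  }, error = function(e) e)
  list(logrank = lr,
       cox = if (inherits(fit, "cox_fit")) fit else NULL,
       cox_error = if (inherits(fit, "error")) conditionMessage(fit)
                   else NULL,
       n_complete_case_dropped = n_dropped,
       isoform = iso_name, endpoint = endpoint)
}

#' Run the full analysis pipeline
#'
#' Executes quantify -> stratify -> group tests -> survival -> protein ->
#' variants, writing each stage's CSV under `cfg$outdir` before the next
#' stage starts. Cancer types failing in a stage are recorded under
#' `$failed` and skipped.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report` list: per-cancer stage results, the variant
#'   tally, and a provenance block (config hash, seed).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  jm <- read_junction_matrix(cfg$junction_file, format = "tsv")
  clin <- utils::read.csv(cfg$clinical_file, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("bcr_patient_barcode", "type", "sample_type", "race")
  if (!all(need %in% names(clin)))
    stop("config error: clinical file lacks column(s): ",
         paste(setdiff(need, names(clin)), collapse = ", "))
  stype <- stats::setNames(clin$sample_type, clin$bcr_patient_barcode)
  et <- quantify_isoforms(jm, cfg$isoforms, cfg$pseudocount,
                          sample_type = stype)
  iso_names <- attr(et, "isoforms")
  report <- list(provenance = list(config_hash = hash, seed = cfg$seed,
                                   package_version = as.character(
                                     utils::packageVersion("pik3r1iso"))),
                 cancers = list(), failed = list())

  for (cc in sort(unique(clin$type))) {
    res <- tryCatch({
      ccl <- clin[clin$type == cc, , drop = FALSE]
      rownames(ccl) <- NULL
      bc <- ccl$bcr_patient_barcode
      ete <- et[match(bc, et$sample_barcode), , drop = FALSE]
      write_expression_csv_path <- file.path(cfg$outdir,
                                             paste0("expression_", cc,
                                                    ".csv"))
      write_stage_csv(as.data.frame(ete), write_expression_csv_path,
                      hash, cfg$seed)
      tum <- ete$sample_type == "tumor"
      nrm <- ete$sample_type == "normal"
      ## stratification
      lab85 <- split_by_mean(ete[[paste0(iso_names[1], "_log")]][tum],
                             bc[tum])
      lab55 <- split_zero_nonzero(ete[[paste0(iso_names[2], "_raw")]][tum],
                                  bc[tum])
      cohorts <- build_cohorts(ccl, lab85)
      ## tumor-vs-normal tests per isoform
      tvn <- lapply(iso_names, function(iso) {
        lg <- ete[[paste0(iso, "_log")]]
        if (sum(nrm) == 0) return(NULL)
        wt <- wilcoxon_rank_sum(lg[tum], lg[nrm], mode = "auto",
                                exact_max_n = cfg$exact_max_n)
        dir <- if (mean(lg[tum]) < mean(lg[nrm])) "tumor_down" else
          "tumor_up"
        list(test = wt, direction = dir)
      })
      names(tvn) <- iso_names
      ## race-group ANOVA: normal vs AA tumor vs EA tumor
      race_anova <- lapply(iso_names, function(iso) {
        lg <- ete[[paste0(iso, "_log")]]
        rc <- cohorts$race
        grp <- list(normal = lg[nrm],
                    AA_tumor = lg[tum & rc == "AA"],
                    EA_tumor = lg[tum & rc == "EA"])
        grp <- grp[vapply(grp, length, 0L) >= 2L]
        if (length(grp) < 2L) return(NULL)
        list(anova = oneway_anova(grp),
             posthoc = pairwise_posthoc(grp))
      })
      names(race_anova) <- iso_names
      ## survival per endpoint and isoform
      surv <- list()
      for (ep in c("OS", "PFI")) {
        if (!all(c(paste0(ep, "_time"), paste0(ep, "_event")) %in%
                 names(ccl))) next
        surv[[paste0(ep, "_", iso_names[1])]] <-
          survival_stage(ccl, lab85, ep, cfg, iso_names[1])
        surv[[paste0(ep, "_", iso_names[2])]] <-
          survival_stage(ccl, lab55, ep, cfg, iso_names[2])
      }
      for (nm in names(surv)) {
        if (!is.null(surv[[nm]]$cox))
          write_stage_csv(forest_table(surv[[nm]]$cox),
                          file.path(cfg$outdir,
                                    paste0("cox_", cc, "_", nm, ".csv")),
                          hash, cfg$seed)
      }
      stats_df <- do.call(rbind, lapply(iso_names, function(iso) {
        w <- tvn[[iso]]
        data.frame(cancer = cc, isoform = iso,
                   test = "wilcoxon_tumor_vs_normal",
                   statistic = if (is.null(w)) NA else
                     unname(w$test$statistic),
                   p_value = if (is.null(w)) NA else w$test$p_value,
                   direction = if (is.null(w)) NA_character_ else
                     w$direction,
                   stringsAsFactors = FALSE)
      }))
      write_stage_csv(stats_df,
                      file.path(cfg$outdir, paste0("tests_", cc, ".csv")),
                      hash, cfg$seed)
      list(expression_summary = list(
             n_tumor = sum(tum), n_normal = sum(nrm),
             mean_log = vapply(iso_names, function(iso)
               mean(ete[[paste0(iso, "_log")]][tum]), 0)),
           labels = list(p85 = lab85, p55 = lab55),
           cohorts = cohorts,
           tumor_vs_normal = tvn, race_anova = race_anova,
           survival = surv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      report$failed[[cc]] <- conditionMessage(res)
    } else {
      report$cancers[[cc]] <- res
    }
  }

  ## protein stage (pan-cohort, grouped by each cancer's p85 labels)
  if (!is.null(cfg$protein_file)) {
    prot <- utils::read.csv(cfg$protein_file, stringsAsFactors = FALSE,
                            comment.char = "#")
    all_labels <- do.call(rbind, lapply(report$cancers, function(r)
      r$labels$p85))
    pres <- protein_by_group(prot, all_labels)
    if (cfg$adjust == "BH")
      pres$p_adj <- stats::p.adjust(pres$p_value, "BH")
    write_stage_csv(pres, file.path(cfg$outdir, "protein_by_group.csv"),
                    hash, cfg$seed)
    report$protein <- pres
  } else {
    report$protein <- "not run"
  }

  ## variant stage
  if (!is.null(cfg$variant_file)) {
    v <- read_variants(cfg$variant_file, format = "tsv")
    tally <- tally_consequences(v, cfg$regions)
    write_tally_csv(tally, file.path(cfg$outdir, "variant_tally.csv"))
    report$variants <- tally
  } else {
    report$variants <- "not run"
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> cancers run:", length(x$cancers),
      "; failed:", length(x$failed),
      "; config:", x$provenance$config_hash, "\n")
  invisible(x)
}
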