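#' Synthetic cohort generation
#'
#' A seeded generator of complete synthetic cohorts with the statistical
#' structure the analysis assumes: negative-binomial junction counts for
#' the abundant isoform with a tumor log2 shift, zero-inflated
#' negative-binomial counts for the alternative-first-exon isoform (the
#' zero/non-zero stratification rule presupposes a point mass at zero),
#' exponential proportional-hazards survival with uniform censoring,
#' Gaussian protein values shifted by isoform group, and a planted variant
#' table. One sub-seed per component stream keeps draws independent across
#' components and byte-reproducible for a given seed.
#'
#' @name synthetic_data
NULL

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the analysis targets: the abundant
#' isoform down-shifted one log2 unit in tumors, the short isoform more
#' often expressed (non-zero) in tumors than normals, 100 tumor and 100
#' normal samples per cancer code, AA/EA race mixture with a small
#' remainder, and proportional-hazards survival in days.
#'
#' @param cancers Cancer type codes to simulate.
#' @param n_tumor,n_normal Samples per cancer.
#' @param race_props Named mixture proportions over AA / EA / other
#'   (tumor samples; must sum to 1).
#' @param p85_mu_normal Negative-binomial mean of the p85a junction count
#'   in normals.
#' @param p85_log2fc_tumor Tumor log2 shift of the p85a mean (negative =
#'   downregulation).
#' @param p85_disp,p55_disp,background_disp NB dispersion (size) parameters.
#' @param p55_pi_normal,p55_pi_tumor Zero-inflation probability (point mass
#'   at zero) of the p55a count in normals / tumors.
#' @param p55_mu NB mean of the positive part of the p55a count.
#' @param n_background,background_mu Number and NB mean of non-informative
#'   background junctions.
#' @param lambda0 Baseline hazard per day.
#' @param beta Named log-hazard coefficients: `group_p85_low` (indicator of
#'   the derived low-p85a group), `age` (per year, centered at 60),
#'   `stage_advanced`, `race_AA`.
#' @param censor_max Upper bound of the uniform censoring time, days.
#' @param prop_advanced,prop_smoker,prop_alcohol Covariate prevalences.
#' @param pfi_hazard_mult Hazard multiplier for the progression endpoint
#'   relative to overall survival.
#' @param protein_effects Named per-protein mean shift of the high-p85a
#'   group (RPPA-like z-score units).
#' @param protein_sd Residual protein SD.
#' @param variant_plant Planted variant counts (data frame with `region`,
#'   `class`, `n`) or NULL for the built-in default plant.
#' @param seed Integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(cancers = "SIMA",
                       n_tumor = 100L, n_normal = 100L,
                       race_props = c(AA = 0.25, EA = 0.70, other = 0.05),
                       p85_mu_normal = 120, p85_log2fc_tumor = -1,
                       p85_disp = 2,
                       p55_pi_normal = 0.7, p55_pi_tumor = 0.35,
                       p55_mu = 25, p55_disp = 1.5,
                       n_background = 20L, background_mu = 50,
                       background_disp = 1,
                       lambda0 = 5e-4,
                       beta = c(group_p85_low = log(2), age = 0.02,
                                stage_advanced = 0.5, race_AA = 0),
                       censor_max = 3650,
                       prop_advanced = 0.4, prop_smoker = 0.4,
                       prop_alcohol = 0.3,
                       pfi_hazard_mult = 1.5,
                       protein_effects = c(AKT_pS473 = -0.8,
                                           mTOR_pS2448 = -0.6,
                                           PTEN = 0.7),
                       protein_sd = 1,
                       variant_plant = NULL,
                       seed = 1L) {
  cfg <- list(cancers = cancers, n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal), race_props = race_props,
              p85_mu_normal = p85_mu_normal,
              p85_log2fc_tumor = p85_log2fc_tumor, p85_disp = p85_disp,
              p55_pi_normal = p55_pi_normal, p55_pi_tumor = p55_pi_tumor,
              p55_mu = p55_mu, p55_disp = p55_disp,
              n_background = as.integer(n_background),
              background_mu = background_mu,
              background_disp = background_disp,
              lambda0 = lambda0, beta = beta, censor_max = censor_max,
              prop_advanced = prop_advanced, prop_smoker = prop_smoker,
              prop_alcohol = prop_alcohol,
              pfi_hazard_mult = pfi_hazard_mult,
              protein_effects = protein_effects, protein_sd = protein_sd,
              variant_plant = variant_plant, seed = as.integer(seed))
  for (f in c("p55_pi_normal", "p55_pi_tumor", "prop_advanced",
              "prop_smoker", "prop_alcohol"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config field `", f, "` must be in [0, 1]")
  if (abs(sum(cfg$race_props) - 1) > 1e-8)
    stop("config field `race_props` must sum to 1")
  for (f in c("p85_disp", "p55_disp", "background_disp", "lambda0",
              "protein_sd"))
    if (cfg[[f]] <= 0) stop("config field `", f, "` must be > 0")
  for (f in c("n_tumor", "n_normal", "n_background"))
    if (cfg[[f]] < 0) stop("config field `", f, "` must be >= 0")
  if (cfg$n_tumor < 2) stop("config field `n_tumor` must be >= 2")
  if (cfg$censor_max <= 0) stop("config field `censor_max` must be > 0")
  structure(cfg, class = "sim_config")
}

# one sub-seed per component stream, derived from the master seed
component_seeds <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 5L),
                  c("clinical", "junctions", "survival", "protein",
                    "variants"))
}

rzinb <- function(n, pi0, mu, size) {
  zero <- stats::rbinom(n, 1L, pi0)
  pos <- stats::rnbinom(n, mu = mu, size = size)
  ifelse(zero == 1L, 0L, pos)
}

#' Simulate a complete synthetic cohort
#'
#' Draw order is fixed per component stream (clinical, junctions,
#' survival, protein, variants), each with its own sub-seed, so identical
#' configurations give byte-identical output. Survival hazards use the
#' low/high p85a group derived from the simulated counts by the mean-split
#' rule, so downstream recovery of the planted log-hazard is exercised on
#' the covariate the pipeline actually sees.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cohort` list: `junctions` (a [junction_matrix()]),
#'   `clinical` (TCGA-CDR-shaped data frame), `protein`, `variants`,
#'   `variant_truth` (expected tally), and `truth` (planted per-sample
#'   labels and linear predictors).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- component_seeds(cfg$seed)
  isoforms <- pik3r1_isoforms()

  ## clinical covariates -------------------------------------------------
  set.seed(seeds[["clinical"]])
  clin_list <- list()
  for (cc in cfg$cancers) {
    nt <- cfg$n_tumor; nn <- cfg$n_normal
    bc_t <- sprintf("%s-T%04d", cc, seq_len(nt))
    bc_n <- if (nn > 0) sprintf("%s-N%04d", cc, seq_len(nn)) else character(0)
    race_t <- sample(names(cfg$race_props), nt, replace = TRUE,
                     prob = cfg$race_props)
    race_str <- c(AA = "black or african american", EA = "white",
                  other = "native american")[race_t]
    clin_list[[cc]] <- data.frame(
      bcr_patient_barcode = c(bc_t, bc_n),
      type = cc,
      sample_type = c(rep("tumor", nt), rep("normal", nn)),
      race = c(unname(race_str), rep("white", nn)),
      age = round(pmin(90, pmax(30, stats::rnorm(nt + nn, 60, 10)))),
      gender = sample(c("female", "male"), nt + nn, replace = TRUE),
      ajcc_stage = c(ifelse(stats::runif(nt) < cfg$prop_advanced,
                            sample(c("Stage III", "Stage IV"), nt, TRUE),
                            sample(c("Stage I", "Stage II"), nt, TRUE)),
                     rep(NA_character_, nn)),
      smoking_history = sample(c("yes", "no"), nt + nn, replace = TRUE,
                               prob = c(cfg$prop_smoker,
                                        1 - cfg$prop_smoker)),
      alcohol_history = sample(c("yes", "no"), nt + nn, replace = TRUE,
                               prob = c(cfg$prop_alcohol,
                                        1 - cfg$prop_alcohol)),
      stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, clin_list)
  rownames(clinical) <- NULL
  is_tumor <- clinical$sample_type == "tumor"
  n_all <- nrow(clinical)

  ## junction counts -----------------------------------------------------
  set.seed(seeds[["junctions"]])
  mu85 <- ifelse(is_tumor, cfg$p85_mu_normal * 2^cfg$p85_log2fc_tumor,
                 cfg$p85_mu_normal)
  c85 <- stats::rnbinom(n_all, mu = mu85, size = cfg$p85_disp)
  pi55 <- ifelse(is_tumor, cfg$p55_pi_tumor, cfg$p55_pi_normal)
  c55 <- rzinb(n_all, pi55, cfg$p55_mu, cfg$p55_disp)
  j85 <- isoforms$p85a$junctions[[1]]
  j55 <- isoforms$p55a$junctions[[1]]
  nb <- cfg$n_background
  bg_start <- 68300000 + 1000 * seq_len(nb)
  jdf <- data.frame(
    chrom = "chr5",
    start = c(j85$start, j55$start, bg_start),
    end = c(j85$end, j55$end, bg_start + 500),
    strand = c(j85$strand, j55$strand,
               rep(c("+", "-"), length.out = nb)),
    stringsAsFactors = FALSE)
  bg_counts <- matrix(stats::rnbinom(nb * n_all, mu = cfg$background_mu,
                                     size = cfg$background_disp),
                      nrow = nb, ncol = n_all)
  counts <- rbind(matrix(c85, nrow = 1), matrix(c55, nrow = 1), bg_counts)
  jm <- junction_matrix(jdf, counts, clinical$bcr_patient_barcode)

  ## derived expression groups (the covariate the pipeline will use) -----
  log85 <- log10(c85 + 1)
  p85_label <- rep(NA_character_, n_all)
  for (cc in cfg$cancers) {
    sel <- is_tumor & clinical$type == cc
    p85_label[sel] <- split_by_mean(log85[sel])$label
  }

  ## survival ------------------------------------------------------------
  set.seed(seeds[["survival"]])
  lp <- ifelse(is.na(p85_label), 0,
               cfg$beta[["group_p85_low"]] * (p85_label == "low")) +
        cfg$beta[["age"]] * (clinical$age - 60) +
        cfg$beta[["stage_advanced"]] *
          (!is.na(clinical$ajcc_stage) &
             clinical$ajcc_stage %in% c("Stage III", "Stage IV")) +
        cfg$beta[["race_AA"]] *
          (normalize_race(clinical$race) == "AA")
  os_true <- stats::rexp(n_all, rate = cfg$lambda0 * exp(lp))
  os_cens <- stats::runif(n_all, 0, cfg$censor_max)
  pfi_true <- stats::rexp(n_all,
                          rate = cfg$lambda0 * cfg$pfi_hazard_mult * exp(lp))
  clinical$OS_time <- round(pmin(os_true, os_cens), 1)
  clinical$OS_event <- as.integer(os_true <= os_cens)
  clinical$PFI_time <- round(pmin(pfi_true, os_cens), 1)
  clinical$PFI_event <- as.integer(pfi_true <= os_cens)
  clinical$OS_time[!is_tumor] <- NA; clinical$OS_event[!is_tumor] <- NA
  clinical$PFI_time[!is_tumor] <- NA; clinical$PFI_event[!is_tumor] <- NA

  ## protein table (tumor samples) ---------------------------------------
  set.seed(seeds[["protein"]])
  bc_t <- clinical$bcr_patient_barcode[is_tumor]
  high_t <- p85_label[is_tumor] == "high"
  protein <- data.frame(sample_barcode = bc_t, stringsAsFactors = FALSE)
  for (pn in names(cfg$protein_effects))
    protein[[pn]] <- cfg$protein_effects[[pn]] * high_t +
      stats::rnorm(length(bc_t), 0, cfg$protein_sd)

  ## variants ------------------------------------------------------------
  set.seed(seeds[["variants"]])
  plant <- cfg$variant_plant
  if (is.null(plant))
    plant <- data.frame(
      region = c("p85a_only", "p85a_only", "p55a_only", "shared"),
      class = c("intron", "missense", "intron", "splice_region"),
      n = c(5L, 2L, 3L, 1L), stringsAsFactors = FALSE)
  vfix <- planted_variant_fixture(plant)

  structure(list(junctions = jm, clinical = clinical, protein = protein,
                 variants = vfix$variants, variant_truth = vfix$expected,
                 cds_example = vfix$cds_example,
                 truth = list(p85_label = stats::setNames(
                                p85_label, clinical$bcr_patient_barcode),
                              linear_predictor = stats::setNames(
                                lp, clinical$bcr_patient_barcode),
                              config = cfg)),
            class = "sim_cohort")
}

#' Generate a variant fixture with known planted tallies
#'
#' Emits a variant table whose region/class tally equals the planted counts
#' exactly. Planted `"shared"` variants are placed at the single coordinate
#' common to both isoform regions; region-only variants at distinct
#' positions strictly inside one region. The fixture also carries a toy CDS
#' whose codon 6 is TGG with a G>T substitution at coding position 18 — the
#' tryptophan-to-cysteine missense worked example for
#' [annotate_coding_snv()].
#'
#' @param plant Data frame with columns `region` (one of `p85a_only`,
#'   `p55a_only`, `shared`, `outside`), `class` (a
#'   [consequence_classes()] value), `n` (count >= 0).
#' @param regions As for [classify_region()].
#' @return A list: `variants` (data frame), `expected`
#'   (`consequence_tally`), `cds_example`.
#' @export
planted_variant_fixture <- function(plant, regions = pik3r1_regions()) {
  stopifnot(all(c("region", "class", "n") %in% names(plant)))
  if (any(plant$n < 0)) stop("planted counts must be >= 0")
  bad <- !plant$class %in% consequence_classes()
  if (any(bad)) stop("unknown planted class: ", plant$class[bad][1])
  r1 <- regions[[1]]; r2 <- regions[[2]]
  shared_lo <- max(r1$start, r2$start)
  shared_hi <- min(r1$end, r2$end)
  pools <- list()
  pools[[paste0(names(regions)[1], "_only")]] <-
    setdiff(seq(r1$start, r1$end), seq(shared_lo, shared_hi))
  pools[[paste0(names(regions)[2], "_only")]] <-
    setdiff(seq(r2$start, r2$end), seq(shared_lo, shared_hi))
  pools[["shared"]] <- if (shared_lo <= shared_hi)
    seq(shared_lo, shared_hi) else integer(0)
  pools[["outside"]] <- seq(max(r1$end, r2$end) + 10000,
                            length.out = 10000)
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(plant))) {
    reg <- plant$region[i]; n <- plant$n[i]
    if (n == 0L) next
    pool <- pools[[reg]]
    if (is.null(pool)) stop("unknown planted region '", reg, "'")
    if (length(pool) == 0L)
      stop("no positions available for planted region '", reg, "'")
    # shared variants may repeat the single overlap coordinate with
    # distinct alleles; region-only variants get distinct positions
    pos <- if (length(pool) >= n) pool[seq_len(n)] else
      rep(pool, length.out = n)
    alt <- rep(c("T", "G", "C"), length.out = n)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = r1$chrom, pos = pos, ref = "A", alt = alt,
      rsid = sprintf("rs%07d", 9000000L + idx + seq_len(n)),
      consequence = plant$class[i], stringsAsFactors = FALSE)
    idx <- idx + n
  }
  variants <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
               alt = character(0), rsid = character(0),
               consequence = character(0), stringsAsFactors = FALSE)
  # ref == alt never planted: ref fixed "A", alts in {T,G,C}... except alt G
  variants$alt[variants$ref == variants$alt] <- "C"
  expected <- tally_consequences(variants, regions)
  list(variants = variants, expected = expected,
       cds_example = list(cds = "ATGGCTGAAGATCTATGGTCAGGCTAA",
                          coding_pos = 18L, ref = "G", alt = "T"))
}

#' Write a simulated cohort in the formats the analysis modules read
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(junctions = file.path(dir, "junctions.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             protein = file.path(dir, "protein.csv"),
             variants = file.path(dir, "variants.tsv"))
  write_junction_tsv(cohort$junctions, paths[["junctions"]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$protein, paths[["protein"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(cohort$variants, paths[["variants"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
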