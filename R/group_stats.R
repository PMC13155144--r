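#' Group-comparison statistics
#'
#' The comparisons the analysis runs: an unpaired Wilcoxon rank-sum test
#' (tumor vs normal expression), one-way ANOVA (normal vs AA-tumor vs
#' EA-tumor; protein by isoform group), Tukey HSD post-hoc contrasts, and
#' the 2^-ddCt qRT-PCR fold change. The rank-sum and F statistics are
#' computed from first principles; base R's `wilcox.test`/`aov` serve as
#' independent cross-checks in the test suite only.
#'
#' @name group_stats
NULL

test_result <- function(test, statistic, p_value, n_per_group,
                        method_detail, ...) {
  stopifnot(is.finite(statistic) || is.infinite(statistic))
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n_per_group = n_per_group, method_detail = method_detail,
                 ...),
            class = "pik_test")
}

#' @export
print.pik_test <- function(x, ...) {
  cat("<", x$test, "> statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value),
      " (", x$method_detail, "; n = ",
      paste(x$n_per_group, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact mode enumerates all `choose(n1+n2, n1)` assignments of the
#' combined ranks to the first group and reports the two-sided tail
#' probability of the observed rank sum. The normal approximation uses the
#' tie-corrected variance and a 0.5 continuity correction. `mode = "auto"`
#' picks exact when there are no ties and `n1 + n2 <= exact_max_n`.
#'
#' @param x,y Numeric samples (both non-empty, finite).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_max_n Largest combined sample size for which exact
#'   enumeration is attempted (default 12).
#' @return A `pik_test` result; `statistic` is the rank sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx"),
                              exact_max_n = 12L) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("inputs must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "exact" && has_ties) {
    warning("exact Wilcoxon requested with tied values; using normal approximation")
    mode <- "approx"
  }
  if (mode == "exact" && N > exact_max_n) {
    warning("exact Wilcoxon requested with combined n > ", exact_max_n,
            "; using normal approximation")
    mode <- "approx"
  }
  if (mode == "auto")
    mode <- if (!has_ties && N <= exact_max_n) "exact" else "approx"
  if (mode == "exact") {
    sums <- colSums(matrix(seq_len(N)[utils::combn(N, n1)], nrow = n1))
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    detail <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    nt <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- W - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    detail <- "normal_approximation"
  }
  test_result("wilcoxon_rank_sum", statistic = c(W = W), p_value = p,
              n_per_group = c(n1, n2), method_detail = detail)
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with df (k - 1, N - k). The degenerate case
#' of zero within-group variance is handled explicitly: equal group means
#' give F = 0, p = 1; unequal means give F = Inf, p = 0.
#'
#' @param groups A list of numeric vectors, >= 2 groups with >= 2 values
#'   each.
#' @return A `pik_test` result with `df` recorded.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs at least 2 values")
  if (any(!is.finite(unlist(groups)))) stop("inputs must be finite")
  k <- length(groups)
  ni <- vapply(groups, length, 0L)
  N <- sum(ni)
  mi <- vapply(groups, mean, 0)
  gm <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- k - 1L; dfw <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  test_result("oneway_anova", statistic = c(F = f), p_value = p,
              n_per_group = ni, method_detail = "F", df = c(dfb, dfw),
              ms_within = if (dfw > 0) ssw / dfw else NA_real_)
}

#' Tukey HSD pairwise post-hoc comparisons
#'
#' All pairwise group contrasts with studentized-range (Tukey HSD) adjusted
#' p-values, using the Tukey-Kramer standard error for unequal group
#' sizes. Unadjusted pooled-t p-values are reported alongside.
#'
#' @param groups As for [oneway_anova()].
#' @param method Only `"tukey"` is implemented.
#' @return A data frame with one row per pair: `group_i`, `group_j`,
#'   `diff`, `statistic` (studentized range q), `p_unadj`, `p_adj`.
#' @export
pairwise_posthoc <- function(groups, method = c("tukey")) {
  method <- match.arg(method)
  an <- oneway_anova(groups)          # validates inputs
  k <- length(groups)
  ni <- vapply(groups, length, 0L)
  mi <- vapply(groups, mean, 0)
  dfw <- an$df[2]
  msw <- an$ms_within
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    d <- mi[i] - mi[j]
    if (msw == 0) {
      q <- if (d == 0) 0 else Inf
      p_adj <- if (d == 0) 1 else 0
      p_un <- p_adj
    } else {
      se_q <- sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j]))
      q <- abs(d) / se_q
      p_adj <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
      tstat <- abs(d) / sqrt(msw * (1 / ni[i] + 1 / ni[j]))
      p_un <- 2 * stats::pt(tstat, dfw, lower.tail = FALSE)
    }
    data.frame(group_i = nm[i], group_j = nm[j], diff = d,
               statistic = q, p_unadj = p_un, p_adj = p_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl);
#' the fold change is 2^-ddCt.
#'
#' @param ct_target_case,ct_ref_case Ct values of target and reference gene
#'   in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return A list with `delta_delta_ct` and `fold_change`.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  list(delta_delta_ct = ddct, fold_change = 2^(-ddct))
}

#' Compare protein levels between isoform expression groups
#'
#' One comparison per protein of the 'low' versus 'high' isoform group
#' (one-way ANOVA with k = 2). Missing protein values are dropped per
#' protein, with the retained group sizes recorded; a protein left with
#' fewer than 2 values in either group is skipped with a warning.
#'
#' @param protein_table Data frame with a `sample_barcode` column and one
#'   numeric column per protein.
#' @param labels A `group_labels` data frame with `barcode` and `label`.
#' @return A data frame with one row per protein: `protein`, `n_low`,
#'   `n_high`, `statistic` (F), `p_value`, `skipped`.
#' @export
protein_by_group <- function(protein_table, labels) {
  if (!"sample_barcode" %in% names(protein_table))
    stop("protein table needs a `sample_barcode` column")
  lab <- labels$label[match(protein_table$sample_barcode, labels$barcode)]
  prot_cols <- setdiff(names(protein_table), "sample_barcode")
  res <- lapply(prot_cols, function(p) {
    v <- protein_table[[p]]
    keep <- !is.na(v) & !is.na(lab)
    lo <- v[keep & lab == "low"]
    hi <- v[keep & lab == "high"]
    if (length(lo) < 2L || length(hi) < 2L) {
      warning("protein ", p, " skipped: fewer than 2 values in a group")
      return(data.frame(protein = p, n_low = length(lo), n_high = length(hi),
                        statistic = NA_real_, p_value = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    tr <- oneway_anova(list(low = lo, high = hi))
    data.frame(protein = p, n_low = length(lo), n_high = length(hi),
               statistic = unname(tr$statistic), p_value = tr$p_value,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
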