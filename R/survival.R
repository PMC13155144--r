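#' Survival analysis: Kaplan-Meier, log-rank, Cox proportional hazards
#'
#' The product-limit estimator, the k-sample log-rank test with
#' hypergeometric variance, and Cox regression fitted by Newton-Raphson on
#' the partial likelihood with Efron (default) or Breslow tie handling.
#' These are computed from first principles; the `survival` package serves
#' as an independent oracle in the test suite only.
#'
#' @name survival_analysis
NULL

check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop("no survival records supplied")
  if (length(event) != length(time)) stop("`time` and `event` lengths differ")
  if (any(!is.finite(time))) stop("survival times must be finite")
  if (any(time < 0)) stop("negative survival time at position ",
                          which(time < 0)[1])
  if (!all(event %in% c(0, 1))) stop("`event` must be 0 (censored) or 1")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), a
#' right-continuous step function. Censorings tied with an event time are
#' still at risk for those events (they leave the risk set just after).
#'
#' @param time Follow-up times in days (>= 0, finite).
#' @param event Event indicator: 1 = event, 0 = censored.
#' @return A `km_curve` object: data frame of distinct event times with
#'   `n_risk`, `n_event`, `survival`, plus censoring times and totals as
#'   attributes.
#' @export
km_estimate <- function(time, event) {
  check_surv_input(time, event)
  tj <- sort(unique(time[event == 1]))
  if (length(tj) == 0L) {
    curve <- data.frame(time = numeric(0), n_risk = numeric(0),
                        n_event = numeric(0), survival = numeric(0))
  } else {
    n_risk <- vapply(tj, function(t) sum(time >= t), 0)
    n_event <- vapply(tj, function(t) sum(time == t & event == 1), 0)
    curve <- data.frame(time = tj, n_risk = n_risk, n_event = n_event,
                        survival = cumprod(1 - n_event / n_risk))
  }
  structure(curve,
            censor_times = sort(time[event == 0]),
            n = length(time), n_events = sum(event),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param t Times at which to evaluate S(t); S = 1 before the first event.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  if (nrow(km) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, km$time)
  c(1, km$survival)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", attr(x, "n"), ", events = ", attr(x, "n_events"),
      ", distinct event times = ", nrow(x), "\n", sep = "")
  invisible(x)
}

#' k-sample log-rank test
#'
#' At each distinct event time the observed group event counts are compared
#' with their hypergeometric expectations given the risk sets; the
#' chi-square statistic is the quadratic form of (O - E) in the summed
#' hypergeometric covariance, on groups - 1 degrees of freedom. For two
#' groups this is (O1 - E1)^2 / V.
#'
#' @param time,event As for [km_estimate()], pooled over groups.
#' @param group Group membership vector (>= 2 groups, each non-empty).
#' @return A `pik_test` result with fields `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.factor(group)
  if (length(group) != length(time)) stop("`group` length differs from `time`")
  k <- nlevels(group)
  if (k < 2L) stop("log-rank needs at least 2 groups")
  ni_tot <- table(group)
  tj <- sort(unique(time[event == 1]))
  if (length(tj) == 0L) {
    warning("no events in any group; log-rank p set to 1")
    return(test_result("logrank", statistic = c(chisq = 0), p_value = 1,
                       n_per_group = as.integer(ni_tot),
                       method_detail = "chi-square", df = k - 1L,
                       observed = rep(0, k), expected = rep(0, k)))
  }
  # at-risk and event counts per group at each distinct event time
  lev <- levels(group)
  ngj <- vapply(lev, function(g) {
    tg <- time[group == g]
    colSums(outer(tg, tj, ">="))
  }, numeric(length(tj)))
  ngj <- matrix(ngj, nrow = length(tj), ncol = k)
  dgj <- vapply(lev, function(g) {
    te <- time[group == g & event == 1]
    tabulate(match(te, tj), nbins = length(tj))
  }, numeric(length(tj)))
  dgj <- matrix(dgj, nrow = length(tj), ncol = k)
  nj <- rowSums(ngj)
  dj <- rowSums(dgj)
  O <- colSums(dgj)
  E <- colSums(dj * ngj / nj)
  # hypergeometric covariance summed over event times
  V <- matrix(0, k, k)
  w <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
  for (g in seq_len(k)) {
    for (h in seq_len(g)) {
      V[g, h] <- sum(w * (ngj[, g] / nj) * ((g == h) - ngj[, h] / nj))
      V[h, g] <- V[g, h]
    }
  }
  d0 <- (O - E)[-k]
  V0 <- V[-k, -k, drop = FALSE]
  Vinv <- tryCatch(solve(V0), error = function(e) MASS::ginv(V0))
  chisq <- drop(t(d0) %*% Vinv %*% d0)
  if (!is.finite(chisq) || chisq < 0) chisq <- 0
  test_result("logrank", statistic = c(chisq = chisq),
              p_value = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
              n_per_group = as.integer(ni_tot),
              method_detail = "chi-square", df = k - 1L,
              observed = unname(O), expected = unname(E),
              variance = V)
}

#' Build a numeric design matrix from clinical covariates
#'
#' Numeric columns pass through; character/factor columns are one-hot
#' encoded against a reference level (first alphabetical unless given in
#' `reference`). Constant columns are a design error.
#'
#' @param data Data frame of covariates.
#' @param reference Named list/vector: reference level per factor column.
#' @return Numeric matrix with `reference_levels` attribute.
#' @export
build_design <- function(data, reference = list()) {
  cols <- list()
  refs <- character(0)
  for (nm in names(data)) {
    v <- data[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      v <- as.character(v)
      lev <- sort(unique(v))
      ref <- if (!is.null(reference[[nm]])) reference[[nm]] else lev[1]
      if (!ref %in% lev)
        stop("reference level '", ref, "' not present in column ", nm)
      refs[nm] <- ref
      for (l in setdiff(lev, ref))
        cols[[paste0(nm, "_", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X, 2, function(c0) length(unique(c0)) == 1L)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  attr(X, "reference_levels") <- refs
  X
}

# Partial log-likelihood, score and information at beta.
# Efron: the d_j tied events at one time each see the risk-set sums with the
# tied-event sums progressively downweighted by l/d_j, l = 0..d_j-1.
cox_loglik <- function(beta, time, event, X, ties) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  tj <- sort(unique(time[event == 1]))
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t0 in tj) {
    R <- time >= t0
    D <- time == t0 & event == 1
    dj <- sum(D)
    wR <- w[R]; XR <- X[R, , drop = FALSE]
    S0 <- sum(wR)
    S1 <- colSums(wR * XR)
    S2 <- crossprod(XR, wR * XR)
    wD <- w[D]; XD <- X[D, , drop = FALSE]
    S0D <- sum(wD)
    S1D <- colSums(wD * XD)
    S2D <- crossprod(XD, wD * XD)
    ll <- ll + sum(eta[D])
    for (l in seq_len(dj) - 1L) {
      phi <- if (ties == "efron") l / dj else 0
      s0 <- S0 - phi * S0D
      s1 <- S1 - phi * S1D
      s2 <- S2 - phi * S2D
      ll <- ll - log(s0)
      U <- U - s1 / s0
      I <- I + s2 / s0 - tcrossprod(s1 / s0)
    }
    U <- U + colSums(XD)
  }
  list(loglik = ll, score = U, information = I)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with Efron
#' (default) or Breslow handling of tied event times. Convergence is
#' declared when the largest absolute score component falls below `tol`
#' (default 1e-9), within at most `max_iter` iterations. Wald 95%
#' confidence intervals are beta +/- 1.96 SE. A coefficient diverging past
#' |beta| > 20 signals a monotone partial likelihood (complete separation)
#' and is an error naming the covariate.
#'
#' @param time,event As for [km_estimate()].
#' @param covariates Data frame or numeric matrix of covariates; factors
#'   are encoded with [build_design()].
#' @param ties `"efron"` or `"breslow"`.
#' @param reference Passed to [build_design()].
#' @param tol,max_iter Convergence control.
#' @return A `cox_fit` object: coefficient table (`term`, `beta`, `HR`,
#'   `se`, `ci_low`, `ci_high`, `z`, `p`) plus model metadata.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    reference = list(), tol = 1e-9, max_iter = 100L) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  if (sum(event) < 1) stop("Cox regression needs at least one event")
  X <- if (is.matrix(covariates)) {
    const <- apply(covariates, 2, function(c0) length(unique(c0)) == 1L)
    if (any(const))
      stop("constant covariate column(s): ",
           paste(colnames(covariates)[const], collapse = ", "))
    covariates
  } else build_design(as.data.frame(covariates), reference)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(time)) stop("covariate rows differ from `time` length")
  p <- ncol(X)
  beta <- numeric(p)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- cox_loglik(beta, time, event, X, ties)
    if (any(abs(beta) > 20))
      stop("monotone partial likelihood (separation) for covariate ",
           colnames(X)[which.max(abs(beta))],
           "; coefficient diverges")
    if (max(abs(fit$score)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    step <- tryCatch(solve(fit$information, fit$score),
                     error = function(e)
                       stop("singular information matrix; check the design"))
    # step-halving if the likelihood does not improve
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- cox_loglik(cand, time, event, X, ties)$loglik
      if (llc >= fit$loglik - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    beta <- beta + h * step
    ll_prev <- fit$loglik
  }
  se <- sqrt(diag(solve(fit$information)))
  z <- beta / se
  tab <- data.frame(term = colnames(X), beta = beta, HR = exp(beta),
                    se = se,
                    ci_low = exp(beta - 1.959963984540054 * se),
                    ci_high = exp(beta + 1.959963984540054 * se),
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, ties = ties, n = length(time),
                 n_events = sum(event), converged = converged,
                 iterations = iter, loglik = fit$loglik,
                 score = fit$score, information = fit$information,
                 reference_levels = attr(X, "reference_levels")),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n = ", x$n, ", events = ", x$n_events, ", ties = ",
      x$ties, ", converged = ", x$converged,
      " (", x$iterations, " iterations)\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Cox partial-likelihood score test at beta = 0
#'
#' The score chi-square U(0)' I(0)^-1 U(0). With a single binary covariate,
#' two-group data and no tied event times this equals the two-group
#' log-rank chi-square, which the test suite uses as a cross-module check.
#'
#' @inheritParams cox_fit
#' @return A `pik_test` result.
#' @export
cox_score_test <- function(time, event, covariates,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  X <- if (is.matrix(covariates)) covariates
       else build_design(as.data.frame(covariates))
  fit <- cox_loglik(numeric(ncol(X)), time, event, X, ties)
  chisq <- drop(t(fit$score) %*% solve(fit$information, fit$score))
  test_result("cox_score", statistic = c(chisq = chisq),
              p_value = stats::pchisq(chisq, ncol(X), lower.tail = FALSE),
              n_per_group = length(time), method_detail = "chi-square",
              df = ncol(X))
}

sig_stars <- function(p) {
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", ""))))
}

#' Forest-plot table of hazard ratios
#'
#' One row per covariate level with HR, 95% CI, Wald p and significance
#' stars (four tiers at 0.05 / 0.01 / 0.001 / 0.0001). Reference levels of
#' encoded factors are shown with HR 1 and an empty CI. Non-converged fits
#' are refused.
#'
#' @param fit A `cox_fit`.
#' @return A data frame: `term`, `HR`, `ci_low`, `ci_high`, `p`, `stars`.
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to tabulate a non-converged Cox fit")
  tab <- fit$coefficients
  out <- data.frame(term = tab$term, HR = tab$HR, ci_low = tab$ci_low,
                    ci_high = tab$ci_high, p = tab$p,
                    stars = sig_stars(tab$p), stringsAsFactors = FALSE)
  refs <- fit$reference_levels
  if (length(refs) > 0) {
    ref_rows <- data.frame(term = paste0(names(refs), "_", refs,
                                         " (reference)"),
                           HR = 1, ci_low = NA_real_, ci_high = NA_real_,
                           p = NA_real_, stars = "",
                           stringsAsFactors = FALSE)
    out <- rbind(ref_rows, out)
  }
  rownames(out) <- NULL
  out
}
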