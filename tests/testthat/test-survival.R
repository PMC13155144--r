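test_that("Kaplan-Meier product-limit matches the hand computation", {
  km <- km_estimate(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km$time, c(2, 6))
  expect_equal(km$survival, c(2 / 3, 0))     # (1 - 1/3), then (1 - 1/1)
  expect_equal(km_survival_at(km, c(1, 2, 5.9, 6)), c(1, 2 / 3, 2 / 3, 0))
  # all censored: S identically 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km2), 0L)
  expect_equal(km_survival_at(km2, c(0, 10)), c(1, 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "no survival records")
  expect_error(km_estimate(c(1, -2), c(1, 1)), "negative")
})

test_that("KM with no censoring equals one minus the ECDF", {
  set.seed(41)
  for (i in 1:10) {
    t0 <- round(rexp(sample(10:60, 1), 0.1), 2)  # rounded => some ties
    km <- km_estimate(t0, rep(1, length(t0)))
    ec <- ecdf(t0)
    expect_equal(km$survival, 1 - ec(km$time), tolerance = 1e-12)
  }
})

test_that("censorings tied with events stay at risk for those events", {
  # event and censoring both at t = 5: the censored subject is in the risk set
  km <- km_estimate(c(5, 5, 8), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3, 1))
})

test_that("log-rank matches the 4-subject hand computation", {
  lt <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(unname(lt$statistic), 49 / 17, tolerance = 1e-10)
  expect_equal(lt$observed[1], 2)
  expect_equal(lt$expected[1], 5 / 6, tolerance = 1e-12)
})

test_that("log-rank degenerate and symmetry properties hold", {
  # identical groups: statistic ~ 0
  t0 <- c(1, 3, 5, 7); e0 <- c(1, 0, 1, 1)
  lt <- logrank_test(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 4))
  expect_equal(unname(lt$statistic), 0, tolerance = 1e-12)
  expect_equal(lt$p_value, 1, tolerance = 1e-10)
  # all censored
  expect_warning(lt0 <- logrank_test(c(1, 2), c(0, 0), c("A", "B")),
                 "no events")
  expect_equal(lt0$p_value, 1)
  # symmetric in group labeling
  set.seed(42)
  t1 <- rexp(40); e1 <- rbinom(40, 1, 0.8); g <- rep(0:1, 20)
  expect_equal(unname(logrank_test(t1, e1, g)$statistic),
               unname(logrank_test(t1, e1, 1 - g)$statistic),
               tolerance = 1e-12)
  expect_error(logrank_test(t1, e1, rep(1, 40)), "at least 2 groups")
})

test_that("log-rank agrees with survdiff for 2 and 3 groups with ties", {
  set.seed(43)
  for (k in 2:3) {
    t0 <- round(rexp(90, 0.1), 1)
    e0 <- rbinom(90, 1, 0.7)
    g <- sample(letters[1:k], 90, replace = TRUE)
    mine <- logrank_test(t0, e0, g)
    ref <- survival::survdiff(survival::Surv(t0, e0) ~ g)
    expect_equal(unname(mine$statistic), ref$chisq, tolerance = 1e-8)
  }
})

test_that("Cox fit reproduces coxph coefficients and standard errors", {
  set.seed(44)
  n <- 150
  x <- rbinom(n, 1, 0.4); z <- rnorm(n)
  t0 <- rexp(n, 0.02 * exp(0.8 * x - 0.4 * z))
  cens <- runif(n, 0, 80)
  time <- round(pmin(t0, cens), 0)   # rounding forces tied event times
  ev <- as.integer(t0 <= cens)
  X <- cbind(x = x, z = z)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(time, ev, X, ties = ties)
    ref <- survival::coxph(survival::Surv(time, ev) ~ x + z, ties = ties)
    expect_true(mine$converged)
    expect_equal(mine$coefficients$beta, unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(mine$coefficients$se, unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
    # score at the optimum is numerically zero
    expect_lt(max(abs(mine$score)), 1e-6)
  }
})

test_that("Cox CI covers a recovered binary-covariate hazard ratio of 2", {
  set.seed(45)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.01 * exp(log(2) * x))
  cens <- runif(n, 0, 400)    # roughly 20% censoring
  fit <- cox_fit(pmin(t0, cens), as.integer(t0 <= cens),
                 matrix(x, dimnames = list(NULL, "x")))
  hr <- fit$coefficients$HR
  expect_gt(hr, 1.7); expect_lt(hr, 2.35)
  expect_lt(fit$coefficients$ci_low, 2)
  expect_gt(fit$coefficients$ci_high, 2)
})

test_that("Cox estimate is equivariant under covariate scaling", {
  set.seed(46)
  n <- 120
  z <- rnorm(n)
  t0 <- rexp(n, 0.05 * exp(0.5 * z))
  ev <- rep(1L, n)
  f1 <- cox_fit(t0, ev, matrix(z, dimnames = list(NULL, "z")))
  f2 <- cox_fit(t0, ev, matrix(10 * z, dimnames = list(NULL, "z")))
  expect_equal(f2$coefficients$beta, f1$coefficients$beta / 10,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$beta * 10, f1$coefficients$beta,
               tolerance = 1e-6)
})

test_that("Cox design and separation pathologies are refused", {
  t0 <- c(3, 5); ev <- c(1, 1)
  expect_error(cox_fit(t0, ev, matrix(0, 2, 1)), "constant")
  # x = 1 fails first: partial likelihood monotone in beta
  expect_error(cox_fit(c(1, 2), c(1, 1),
                       matrix(c(1, 0), dimnames = list(NULL, "x"))),
               "separation|monotone")
  expect_error(cox_fit(c(1, 2), c(0, 0), matrix(c(1, 0), ncol = 1)),
               "at least one event")
})

test_that("factor encoding uses reference levels and flags constants", {
  df <- data.frame(grp = c("low", "high", "low", "high"),
                   age = c(50, 60, 70, 80))
  X <- build_design(df, reference = list(grp = "high"))
  expect_equal(colnames(X), c("grp_low", "age"))
  expect_equal(unname(X[, "grp_low"]), c(1, 0, 1, 0))
  expect_equal(attr(X, "reference_levels"), c(grp = "high"))
  expect_error(build_design(data.frame(a = c(1, 1, 1))), "constant")
  expect_error(build_design(df, reference = list(grp = "absent")),
               "not present")
})

test_that("score test at zero equals the log-rank chi-square without ties", {
  set.seed(47)
  for (i in 1:10) {
    n <- 50
    g <- rbinom(n, 1, 0.5)
    t0 <- rexp(n, 0.1 * exp(0.3 * g))  # continuous => no ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) == 0 || length(unique(g)) < 2) next
    sc <- cox_score_test(t0, ev, matrix(g, ncol = 1))
    lr <- logrank_test(t0, ev, g)
    expect_equal(unname(sc$statistic), unname(lr$statistic),
                 tolerance = 1e-8)
  }
})

test_that("forest table formats hazard ratios, stars and reference rows", {
  set.seed(48)
  n <- 100
  df <- data.frame(grp = sample(c("low", "high"), n, TRUE),
                   age = rnorm(n, 60, 10))
  t0 <- rexp(n, 0.01 * exp(0.9 * (df$grp == "low")))
  fit <- cox_fit(t0, rep(1L, n), df, reference = list(grp = "high"))
  tab <- forest_table(fit)
  expect_equal(tab$term[1], "grp_high (reference)")
  expect_equal(tab$HR[1], 1)
  expect_true(is.na(tab$ci_low[1]))
  expect_equal(tab$stars[1], "")
  # star tiers
  expect_equal(pik3r1iso:::sig_stars(c(0.2, 0.0322, 0.004, 5e-4, 5e-5)),
               c("", "*", "**", "***", "****"))
  fake <- fit; fake$converged <- FALSE
  expect_error(forest_table(fake), "non-converged")
})
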