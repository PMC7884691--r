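test_that("pooled t test matches the closed-form oracle and prints df = n1+n2-2", {
  x <- c(1, 2, 3)
  y <- c(2, 3, 4)
  res <- group_ttest(x, y)
  # closed form: pooled sd = 1, se = sqrt(2/3)
  expect_equal(res$t, -1 / sqrt(2 / 3))
  expect_equal(res$df, 4)
  expect_equal(res$d, -1)

  same <- group_ttest(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)

  res2 <- group_ttest(rnorm(37), rnorm(71))
  expect_equal(res2$df, 106)

  expect_error(group_ttest(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(group_ttest(1, c(1, 2)), "at least 2")
})

test_that("pooled t test agrees with the formula oracle on random inputs", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n1 <- sample(3:12, 1)
      n2 <- sample(3:12, 1)
      x <- rnorm(n1)
      y <- rnorm(n2, 0.5)
      sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
      t_oracle <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
      res <- group_ttest(x, y)
      expect_equal(res$t, t_oracle)
      expect_equal(res$df, n1 + n2 - 2)
      expect_equal(res$p, 2 * pt(-abs(t_oracle), n1 + n2 - 2))
    }
  })
})

test_that("Spearman rho handles monotone pairs, ties, and transforms", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, rev(1:8))$rho, -1)

  # 5-point toy with a tie: brute-force average-rank oracle
  x <- c(1, 2, 2, 3, 4)
  y <- c(10, 30, 20, 40, 50)
  rx <- c(1, 2.5, 2.5, 4, 5)
  ry <- c(1, 3, 2, 4, 5)
  rho_oracle <- sum((rx - 3) * (ry - 3)) /
    sqrt(sum((rx - 3)^2) * sum((ry - 3)^2))
  expect_equal(spearman_cor(x, y)$rho, rho_oracle)
  expect_equal(spearman_cor(x, y)$rho,
               cor(x, y, method = "spearman"))  # library cross-check

  # invariance under strictly monotone transforms
  withr::with_seed(23, {
    a <- rnorm(30)
    b <- rnorm(30)
  })
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)
  expect_equal(spearman_cor(a, b^3 + 5 * b)$rho, spearman_cor(a, b)$rho)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("Fisher r-to-z comparison matches its closed form", {
  expect_equal(fisher_rz_compare(0.4, 30, 0.4, 50)$z, 0)
  z_oracle <- (atanh(0.5) - atanh(0.2)) / sqrt(1 / 47 + 1 / 47)
  res <- fisher_rz_compare(0.5, 50, 0.2, 50)
  expect_equal(res$z, z_oracle)
  expect_equal(res$p, 2 * pnorm(-abs(z_oracle)))
  expect_error(fisher_rz_compare(1, 30, 0.2, 30), "< 1")
  expect_error(fisher_rz_compare(0.5, 3, 0.2, 30), "n >= 4")
})

test_that("hierarchical regression detects cognition beyond motor score", {
  # constructed signal: cv depends on both scores
  withr::with_seed(31, {
    n <- 70
    mupdrs <- rnorm(n, 13, 7)
    moca <- rnorm(n, 24, 3.5)
    cv <- 0.2 + 0.004 * mupdrs - 0.01 * moca + rnorm(n, 0, 0.02)
    d <- tibble::tibble(cv = cv, mupdrs = mupdrs, moca = moca)
  })
  h <- hierarchical_regression(d)
  expect_lt(h$comparison$p, 0.01)
  expect_equal(h$comparison$df1, 1)
  expect_equal(h$model_stats$model,
               c("cv ~ mupdrs", "cv ~ mupdrs + moca"))
  expect_gt(h$model_stats$r_squared[2], h$model_stats$r_squared[1])
  td <- tidy(h)
  expect_true(all(c("term", "estimate", "model") %in% names(td)))

  # null MOCA: comparison should rarely be significant
  pvals <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      dn <- tibble::tibble(mupdrs = rnorm(60, 13, 7),
                           moca = rnorm(60, 24, 3.5))
      dn$cv <- 0.2 + 0.003 * dn$mupdrs + rnorm(60, 0, 0.02)
    })
    hierarchical_regression(dn)$comparison$p
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.9)

  dup <- d
  dup$moca <- dup$mupdrs
  expect_error(hierarchical_regression(dup), "collinear")
})

test_that("mediation recovers the product of paths and covers the null", {
  withr::with_seed(55, {
    n <- 200
    x <- rnorm(n)
    m <- 0.5 * x + rnorm(n, 0, 0.4)
    y <- 0.8 * m + rnorm(n, 0, 0.4)
    d <- tibble::tibble(power = x, cv = m, moca = y)
  })
  med <- mediation_boot(d, "power", "cv", "moca", seed = 1)
  est <- med$estimates
  acme <- est[est$effect == "ACME", ]
  expect_lt(abs(acme$estimate - 0.4), 0.1)
  expect_true(acme$ci_lower <= 0.4 && 0.4 <= acme$ci_upper)
  expect_lt(acme$p, 0.05)
  # linear decomposition: ACME + ADE = total
  expect_equal(est$estimate[1] + est$estimate[2], est$estimate[3],
               tolerance = 1e-6)

  # null b-path: ACME interval covers zero
  withr::with_seed(56, {
    d0 <- tibble::tibble(power = rnorm(100),
                         cv = numeric(100), moca = rnorm(100))
    d0$cv <- 0.5 * d0$power + rnorm(100, 0, 0.4)
  })
  med0 <- mediation_boot(d0, "power", "cv", "moca", seed = 2)
  a0 <- med0$estimates[med0$estimates$effect == "ACME", ]
  expect_true(a0$ci_lower <= 0 && 0 <= a0$ci_upper)

  expect_error(mediation_boot(d[1:10, ], "power", "cv", "moca"),
               "20 complete cases")
  dd <- d
  dd$cv <- 1
  expect_error(mediation_boot(dd, "power", "cv", "moca"), "degenerate")
})

test_that("bootstrap mediation is reproducible under a seed", {
  withr::with_seed(57, {
    d <- tibble::tibble(power = rnorm(60), cv = rnorm(60),
                        moca = rnorm(60))
  })
  m1 <- mediation_boot(d, "power", "cv", "moca", n_boot = 200, seed = 9)
  m2 <- mediation_boot(d, "power", "cv", "moca", n_boot = 200, seed = 9)
  expect_identical(m1$estimates, m2$estimates)
})

test_that("the trial-wise LMM reports terms, AICs and subject variance", {
  d <- sim_lmm_data(71)
  fit <- lmm_trialwise(d)
  expect_s3_class(fit, "tf_lmm")
  expect_equal(nrow(fit$fixed), 15)   # full 4-way factorial
  expect_true("delta:group:moca" %in% fit$fixed$term)
  expect_true(all(fit$fixed$F >= 0, na.rm = TRUE))
  expect_gte(fit$ranef_var, 0)
  expect_equal(sort(fit$aic$model),
               sort(c("full", "delta", "group", "moca", "interval")))
  # interval dominates keypress, so the full model must beat delta-only
  aic <- setNames(fit$aic$aic, fit$aic$model)
  expect_lt(aic["full"], aic["delta"])
  expect_gt(fit$r_squared, 0.5)
  g <- glance(fit)
  expect_equal(g$n_subjects, 16)

  # intercept-only degenerate case: fitted values near the grand mean
  d0 <- d
  d0$keypress <- 5 + rnorm(nrow(d0), 0, 0.01)
  d0$delta <- rnorm(nrow(d0))
  fit0 <- lmm_trialwise(d0)
  expect_equal(mean(fitted(fit0$model)), mean(d0$keypress),
               tolerance = 1e-3)

  alias <- d
  alias$moca <- alias$delta
  expect_error(lmm_trialwise(alias), "aliased")
})

test_that("a known three-way coefficient is recovered within its Wald CI", {
  d <- sim_lmm_data(72, b_dgm = 0.06)
  fit <- lmm_trialwise(d)
  co <- summary(fit$model)$coefficients
  row <- co["delta:groupPD:moca", ]
  expect_lt(abs(row["Estimate"] - 0.06), 3 * row["Std. Error"])
})

test_that("per-subject slopes recover injected coupling and group labels", {
  # fit within one interval condition (as the analyses do), so the other
  # condition's offset does not inflate the residual; the mean slope then
  # has se ~ 0.018 and the checks sit at ~3 sigma
  d <- dplyr::filter(sim_lmm_data(73, n_sub = 20, n_trial = 80, b_dgm = 0),
                     interval == 7)
  sl <- subject_slopes(d)
  expect_equal(nrow(sl), 20)
  # common within-subject slope 0.05 injected for everyone
  expect_lt(abs(mean(sl$slope) - 0.05), 0.055)
  expect_setequal(unique(sl$group), c("CTL", "PD"))

  # uncorrelated power: slopes centred at zero
  d0 <- d
  withr::with_seed(5, {
    d0$keypress <- rnorm(nrow(d0), 5, 0.5)
  })
  sl0 <- subject_slopes(d0)
  expect_lt(abs(mean(sl0$slope)), 0.055)

  # constant power or too few trials -> NA slope
  few <- d[d$subject == "S01", ][1:3, ]
  few$subject <- "tiny"
  sl_few <- subject_slopes(rbind(d, few))
  expect_true(is.na(sl_few$slope[sl_few$subject == "tiny"]))
})
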