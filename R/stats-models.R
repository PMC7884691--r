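#' Hierarchical regression of timing variability on motor and cognitive
#' scores
#'
#' Fits the nested pair `cv ~ mupdrs` and `cv ~ mupdrs + moca` on complete
#' cases (motor score first, cognition second) and compares them with an
#' ANOVA F test, asking whether cognition explains variability beyond motor
#' impairment.
#'
#' @param data Data frame with columns `cv`, `mupdrs`, `moca`.
#' @return A `tf_hreg` object; see [tidy.tf_hreg()] / [glance.tf_hreg()].
#' @export
hierarchical_regression <- function(data) {
  d <- data[complete.cases(data[, c("cv", "mupdrs", "moca")]), ]
  m1 <- lm(cv ~ mupdrs, data = d)
  m2 <- lm(cv ~ mupdrs + moca, data = d)
  if (qr(stats::model.matrix(m2))$rank < 3) {
    abort("collinear predictors: mupdrs and moca are aliased.")
  }
  cmp <- anova(m1, m2)
  s1 <- summary(m1); s2 <- summary(m2)
  structure(list(
    model1 = m1, model2 = m2, n = nrow(d),
    comparison = tibble(
      F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
      p = cmp$`Pr(>F)`[2]),
    model_stats = tibble(
      model = c("cv ~ mupdrs", "cv ~ mupdrs + moca"),
      F = c(s1$fstatistic[1], s2$fstatistic[1]),
      df1 = c(s1$fstatistic[2], s2$fstatistic[2]),
      df2 = c(s1$fstatistic[3], s2$fstatistic[3]),
      r_squared = c(s1$r.squared, s2$r.squared),
      aic = c(AIC(m1), AIC(m2)))),
    class = "tf_hreg")
}

#' @export
print.tf_hreg <- function(x, ...) {
  cat("<tf_hreg> nested model comparison (n =", x$n, ")\n")
  print(x$model_stats)
  cat(sprintf("added term: F(%d, %d) = %.3g, p = %.3g\n",
              x$comparison$df1, x$comparison$df2, x$comparison$F,
              x$comparison$p))
  invisible(x)
}

#' @rdname hierarchical_regression
#' @param x A `tf_hreg` object.
#' @param ... Unused.
#' @export
tidy.tf_hreg <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(broom_lm(x$model1), model = "cv ~ mupdrs"),
    dplyr::mutate(broom_lm(x$model2), model = "cv ~ mupdrs + moca"))
}

#' @rdname hierarchical_regression
#' @export
glance.tf_hreg <- function(x, ...) {
  dplyr::bind_cols(x$comparison, tibble(n = x$n))
}

# minimal lm coefficient tidier (term/estimate/se/t/p)
broom_lm <- function(m) {
  co <- summary(m)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std_error = co[, 2],
         statistic = co[, 3], p_value = co[, 4])
}

#' Bootstrap causal mediation analysis
#'
#' Linear product-of-paths mediation: the mediator model `m ~ x` gives the
#' a-path, the outcome model `y ~ x + m` gives the b-path and the direct
#' effect. The average causal mediation effect is ACME = a * b and the
#' total effect ACME + ADE (exact for linear models without interaction).
#' Uncertainty comes from a case (row) bootstrap with percentile intervals.
#'
#' @param data Data frame.
#' @param treat,mediator,outcome Column names for the x, m, y roles (e.g.
#'   delta power -> timing CV -> cognitive score).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf_level Interval coverage (default 0.95).
#' @param seed Optional seed for the bootstrap stream.
#' @return A `tf_mediation` object; `tidy()` returns rows for ACME, ADE
#'   and the total effect with CIs and bootstrap p values.
#' @export
mediation_boot <- function(data, treat, mediator, outcome,
                           n_boot = 1000, conf_level = 0.95, seed = NULL) {
  d <- data[complete.cases(data[, c(treat, mediator, outcome)]),
            c(treat, mediator, outcome)]
  names(d) <- c("x", "m", "y")
  if (nrow(d) < 20) abort("mediation needs at least 20 complete cases.")
  if (sd(d$x) == 0 || sd(d$m) == 0 || sd(d$y) == 0) {
    abort("degenerate variance in a mediation variable.")
  }
  paths <- function(dd) {
    a <- coef(lm(m ~ x, data = dd))[["x"]]
    fy <- lm(y ~ x + m, data = dd)
    b <- coef(fy)[["m"]]
    ade <- coef(fy)[["x"]]
    c(acme = a * b, ade = ade, total = a * b + ade)
  }
  est <- paths(d)
  boot <- matrix(0, n_boot, 3)
  draw <- function() {
    for (i in seq_len(n_boot)) {
      boot[i, ] <<- paths(d[sample.int(nrow(d), replace = TRUE), ])
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(boot) <- names(est)
  alpha <- 1 - conf_level
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  pval <- vapply(seq_along(est), function(j) {
    2 * min(mean(boot[, j] <= 0), mean(boot[, j] >= 0))
  }, 0)
  structure(list(
    estimates = tibble(
      effect = c("ACME", "ADE", "total"),
      estimate = unname(est),
      ci_lower = ci[1, ], ci_upper = ci[2, ], p = pmin(1, pval)),
    n = nrow(d), n_boot = n_boot, conf_level = conf_level,
    roles = c(treat = treat, mediator = mediator, outcome = outcome)),
    class = "tf_mediation")
}

#' @export
print.tf_mediation <- function(x, ...) {
  cat(sprintf("<tf_mediation> %s -> %s -> %s (n = %d, %d resamples)\n",
              x$roles["treat"], x$roles["mediator"], x$roles["outcome"],
              x$n, x$n_boot))
  print(x$estimates)
  invisible(x)
}

#' @rdname mediation_boot
#' @param x A `tf_mediation` object.
#' @param ... Unused.
#' @export
tidy.tf_mediation <- function(x, ...) x$estimates

#' @rdname mediation_boot
#' @export
glance.tf_mediation <- function(x, ...) {
  tibble(n = x$n, n_boot = x$n_boot, conf_level = x$conf_level)
}

#' Trial-wise linear mixed-effects model
#'
#' Models single-trial keypress time by the full factorial of cue-evoked
#' delta dB power, disease group, MOCA and interval, with a per-participant
#' random intercept:
#' `keypress ~ delta * group * moca * interval + (1 | subject)`.
#' Fitted by maximum likelihood so AIC comparisons across fixed-effect
#' structures are valid; per-term F tests use Satterthwaite denominator
#' degrees of freedom (type III). Also fits the four single-covariate
#' models for AIC comparison.
#'
#' @param data Trial-level data frame with columns `keypress`, `delta`,
#'   `group`, `moca`, `interval`, `subject`; >= 2 subjects with >= 2 trials.
#' @return A `tf_lmm` object: the `lmerMod` fit, a type-III F table, an
#'   AIC comparison tibble, the random-intercept variance, and R^2
#'   (squared correlation of fitted and observed keypress).
#' @export
lmm_trialwise <- function(data) {
  need <- c("keypress", "delta", "group", "moca", "interval", "subject")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  d <- data[complete.cases(data[, need]), need]
  d$group <- factor(d$group)
  d$subject <- factor(d$subject)
  if (nlevels(d$subject) < 2) abort("need >= 2 subjects.")
  if (min(table(d$subject)) < 2) abort("every subject needs >= 2 trials.")

  mm <- stats::model.matrix(~ delta * group * moca * interval, d)
  if (qr(mm)$rank < ncol(mm)) {
    bad <- colnames(mm)[qr(mm)$pivot[-seq_len(qr(mm)$rank)]]
    abort(paste("rank-deficient fixed effects; aliased term(s):",
                paste(bad, collapse = ", ")))
  }

  full <- lmerTest::lmer(
    keypress ~ delta * group * moca * interval + (1 | subject),
    data = d, REML = FALSE)
  an <- anova(full, type = 3)
  fixed_f <- tibble(term = rownames(an), df_num = an$NumDF,
                    df_den = an$DenDF, F = an$`F value`, p = an$`Pr(>F)`)

  single <- purrr::map_dbl(
    c(delta = "delta", group = "group", moca = "moca",
      interval = "interval"),
    function(v) {
      AIC(lme4::lmer(stats::reformulate(c(v, "(1 | subject)"),
                                        response = "keypress"),
                     data = d, REML = FALSE))
    })
  aic_tbl <- tibble(model = c("full", names(single)),
                    aic = c(AIC(full), unname(single)))
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(
    model = full, fixed = fixed_f, aic = aic_tbl,
    ranef_var = vc$vcov[vc$grp == "subject"],
    r_squared = cor(fitted(full), d$keypress)^2,
    n_trials = nrow(d), n_subjects = nlevels(d$subject)),
    class = "tf_lmm")
}

#' @export
print.tf_lmm <- function(x, ...) {
  cat(sprintf("<tf_lmm> %d trials, %d subjects, R^2 = %.2f, subject var = %.3g\n",
              x$n_trials, x$n_subjects, x$r_squared, x$ranef_var))
  print(x$fixed, n = Inf)
  invisible(x)
}

#' @rdname lmm_trialwise
#' @param x A `tf_lmm` object.
#' @param ... Unused.
#' @export
tidy.tf_lmm <- function(x, ...) x$fixed

#' @rdname lmm_trialwise
#' @export
glance.tf_lmm <- function(x, ...) {
  tibble(r_squared = x$r_squared, ranef_var = x$ranef_var,
         aic = x$aic$aic[x$aic$model == "full"],
         n_trials = x$n_trials, n_subjects = x$n_subjects)
}

#' Per-subject slopes of keypress on delta power
#'
#' Ordinary least-squares slope of keypress time on single-trial delta dB,
#' fitted within each subject with at least `min_trials` trials and
#' non-constant power; the per-individual visualization companion to
#' [lmm_trialwise()].
#'
#' @param data Trial-level data frame (as for [lmm_trialwise()]).
#' @param min_trials Minimum trials per subject (default 5).
#' @return A tibble: `subject`, `group`, `slope` (s/dB), `se`, `n`.
#' @export
subject_slopes <- function(data, min_trials = 5) {
  data |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_trials || sd(d$delta) == 0) {
        return(tibble(slope = NA_real_, se = NA_real_, n = nrow(d)))
      }
      co <- summary(lm(keypress ~ delta, data = d))$coefficients
      tibble(slope = co["delta", 1], se = co["delta", 2], n = nrow(d))
    }) |>
    dplyr::ungroup()
}
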