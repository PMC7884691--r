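test_that("cohort generation respects counts, bounds and determinism", {
  p <- profile_paper_default(seed = 5)

  empty <- p
  empty$n_control <- 0
  empty$n_pd <- 0
  expect_equal(nrow(simulate_cohort(empty)), 0)

  coh <- simulate_cohort(p)
  expect_equal(sum(coh$group == "CTL"), 37)
  expect_equal(sum(coh$group == "PD"), 71)
  expect_true(all(coh$moca >= 0 & coh$moca <= 30))
  expect_true(all(coh$moca == round(coh$moca)))
  expect_true(all(coh$latent_cv > 0))
  expect_true(all(is.na(coh$mupdrs[coh$group == "CTL"])))
  expect_true(all(coh$mupdrs[coh$group == "PD"] >= 0))
  # 3-s completion emulates the study attrition
  expect_equal(sum(coh$complete_3 & coh$group == "PD"), 52)
  expect_equal(sum(coh$complete_3 & coh$group == "CTL"), 31)

  expect_identical(coh, simulate_cohort(p))
  expect_false(identical(coh, simulate_cohort(p, seed = 6)))

  bad <- p
  bad$n_pd <- -1
  expect_error(simulate_cohort(bad), "n_pd")
})

test_that("PD latent variability decreases with MOCA when the link is negative", {
  hits <- vapply(1:20, function(s) {
    coh <- simulate_cohort(profile_paper_default(seed = s))
    pd <- coh[coh$group == "PD", ]
    spearman_cor(pd$moca, pd$latent_cv)$rho < 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("behavior draws have the configured mean, truncation and zero-noise limit", {
  p <- tiny_profile(n_ctl = 3, n_pd = 3)
  coh <- simulate_cohort(p)

  coh0 <- coh
  coh0$latent_cv <- 1e-12
  tr0 <- simulate_behavior(coh0, p, 7, n_trials = 5)
  expect_equal(tr0$keypress, rep(6.4, nrow(tr0)) *
                 ifelse(tr0$group == "CTL", 6.1 / 6.4, 1),
               tolerance = 1e-6)

  expect_error(simulate_behavior(coh, p, 5), "unknown interval")
  expect_error(simulate_behavior(coh, p, 7, n_trials = 0), ">= 1")

  tr <- simulate_behavior(coh, p, 7, n_trials = 30)
  expect_true(all(tr$keypress > 0.2))
  expect_equal(max(tr$block), 2L)  # 30 trials -> blocks of 20
  expect_identical(tr, simulate_behavior(coh, p, 7, n_trials = 30))
})

test_that("pooled PD 7-s keypress mean lands near 6.4 s", {
  p <- profile_paper_default(seed = 3)
  coh <- simulate_cohort(p)
  tr <- simulate_behavior(coh, p, 7)
  pd <- tr[tr$group == "PD", ]
  expect_equal(mean(pd$keypress), 6.4, tolerance = 0.1 / 6.4)
})

test_that("normal draws at the PD 7-s parameters reproduce CV 0.22 (Monte-Carlo oracle)", {
  withr::with_seed(99, {
    r <- rnorm(1e6, 6.4, 1.408)
    expect_lt(abs(sd(r) / mean(r) - 0.22), 0.003)
  })
})

test_that("rescaling means and sds together leaves the empirical CV unchanged", {
  p <- tiny_profile(n_ctl = 0, n_pd = 30)
  coh <- simulate_cohort(p)
  cv_of <- function(pp) {
    tr <- simulate_behavior(coh, pp, 7, n_trials = 60, seed = 4)
    s <- keypress_summary(tr)
    mean(s$cv)
  }
  p2 <- p
  p2$behavior$mean_keypress <- p$behavior$mean_keypress * 3
  p2$behavior$sd_keypress <- p$behavior$sd_keypress * 3
  expect_equal(cv_of(p), cv_of(p2), tolerance = 1e-2)
})

test_that("EEG epochs have the specified geometry and are reproducible", {
  p <- tiny_profile(n_ctl = 1, n_pd = 1)
  p$epoch_window <- list(`3` = c(-2, 10), `7` = c(-2, 20))
  coh <- simulate_cohort(p)
  tr <- simulate_behavior(coh, p, 7, n_trials = 3)
  eps <- simulate_eeg_epochs(coh, tr, p)
  expect_length(eps, 2)
  expect_equal(dim(eps[[1]]$data), c(3, 1, 11000))  # -2..20 s at 500 Hz
  expect_equal(eps[[1]]$t0, -2)
  expect_identical(eps, simulate_eeg_epochs(coh, tr, p))

  orphan <- tr
  orphan$subject[1] <- "nobody"
  expect_error(simulate_eeg_epochs(coh, orphan, p), "mismatched ids")

  mixed <- rbind(tr, simulate_behavior(coh, p, 3, n_trials = 2))
  expect_error(simulate_eeg_epochs(coh, mixed, p), "single interval")
})

test_that("noise-only epochs show a pink (1/f) spectrum", {
  p <- profile_null(n_subjects = 1, seed = 21)
  coh <- simulate_cohort(p)
  tr <- simulate_behavior(coh, p, 7, n_trials = 20)
  ep <- simulate_eeg_epochs(coh, tr, p)[[1]]
  # average periodogram over trials, fit log-log slope over 2-40 Hz
  n <- dim(ep$data)[3]
  f <- (seq_len(n) - 1) * ep$fs / n
  pxx <- rowMeans(vapply(seq_len(dim(ep$data)[1]), function(i) {
    Mod(fft(ep$data[i, 1, ]))^2
  }, numeric(n)))
  sel <- f >= 2 & f <= 40
  slope <- coef(lm(log10(pxx[sel]) ~ log10(f[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("trial burst gain is anticorrelated with keypress error", {
  p <- tiny_profile(n_ctl = 0, n_pd = 1, seed = 8)
  p$trial_coupling <- 0.6
  p$phase_locking_frac <- 1
  coh <- simulate_cohort(p)
  coh$latent_gain <- 2
  tr <- simulate_behavior(coh, p, 7, n_trials = 200)
  ep <- simulate_eeg_epochs(coh, tr, p)[[1]]
  # recover the trial burst amplitude by projecting on the known template
  tax <- epoch_times(ep)
  env <- exp(-(tax - p$burst_center)^2 / (2 * p$burst_width^2))
  tmpl <- env * cos(2 * pi * p$burst_freq * (tax - p$burst_center))
  amp <- as.vector(ep$data[, 1, ] %*% tmpl) / sum(tmpl^2)
  err <- abs(tr$keypress - 7)
  expect_lt(cor(amp, err), -0.2)
})

test_that("profile validation rejects inconsistent settings", {
  expect_error(tiny_profile() |> (\(p) {
    p$phase_locking_frac <- 1.2
    timefront:::validate_profile(p)
  })(), "phase_locking_frac")
  expect_error(tiny_profile() |> (\(p) {
    p$behavior$sd_keypress[1] <- 0
    timefront:::validate_profile(p)
  })(), "positive")
  expect_error(tiny_profile() |> (\(p) {
    p$fs <- 4
    timefront:::validate_profile(p)
  })(), "fs")
})
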