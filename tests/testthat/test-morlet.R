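test_that("the wavelet bank spans 1-50 Hz in 50 log steps with 3-10 cycles", {
  bank <- morlet_bank(fs = 500)
  expect_length(bank$freqs, 50)
  expect_equal(bank$freqs[1], 1)
  expect_equal(bank$freqs[50], 50)
  expect_true(all(diff(bank$freqs) > 0))
  expect_true(all(diff(log10(bank$freqs)) - diff(log10(bank$freqs))[1] <
                    1e-12))
  expect_equal(bank$cycles[1], 3)
  expect_equal(bank$cycles[50], 10)
  expect_true(all(diff(bank$cycles) >= 0))
  expect_equal(bank$sigma, bank$cycles / (2 * pi * bank$freqs))
  expect_error(morlet_bank(fs = 60), "too low")
})

test_that("FFT-based decomposition equals direct time-domain convolution", {
  fs <- 500
  bank <- morlet_bank(fs = fs)
  withr::with_seed(101, {
    x <- rnorm(2 * fs)
  })
  ep <- epoch_set(array(x, dim = c(1, 1, length(x))), fs = fs, t0 = -1,
                  channels = "Cz")
  tfr <- morlet_tfr(ep, bank, channel = "Cz")
  oracle <- direct_morlet(x, bank)
  rel <- abs(tfr$power[1, , ] - Mod(oracle)^2) /
    pmax(Mod(oracle)^2, .Machine$double.eps)
  expect_lt(max(rel), 1e-9)
  # phase agrees too (where magnitude is non-negligible)
  big <- Mod(oracle) > 1e-8
  dphi <- abs(tfr$phase[1, , ][big] - Arg(oracle)[big])
  expect_lt(max(pmin(dphi, 2 * pi - dphi)), 1e-6)
})

test_that("a pure sinusoid peaks at the nearest bank frequency", {
  fs <- 500
  bank <- morlet_bank(fs = fs)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ep <- epoch_set(array(sin(2 * pi * 10 * t), dim = c(1, 1, length(t))),
                  fs = fs, t0 = 0, channels = "Cz")
  tfr <- morlet_tfr(ep, bank, window = c(1, 3))  # avoid edges
  prof <- apply(tfr$power[1, , ], 1, mean)
  expect_equal(which.max(prof), which.min(abs(bank$freqs - 10)))
  # unit amplitude -> analytic power ~ 1 at the peak
  expect_equal(max(prof), 1, tolerance = 0.05)

  zero <- epoch_set(array(0, dim = c(1, 1, length(t))), fs = fs, t0 = 0,
                    channels = "Cz")
  expect_equal(max(morlet_tfr(zero, bank)$power), 0)
})

test_that("power scales quadratically and dB differences are amplitude-invariant", {
  fs <- 500
  bank <- morlet_bank(n_freq = 12, f_range = c(2, 30), fs = fs)
  withr::with_seed(7, {
    x <- rnorm(3 * fs)
  })
  mk <- function(k) {
    ep <- epoch_set(array(k * rep(x, 2), dim = c(2, 1, length(x))),
                    fs = fs, t0 = -1, channels = "Cz")
    morlet_tfr(ep, bank, window = c(-0.5, 1))
  }
  t1 <- mk(1)
  t3 <- mk(3)
  expect_equal(t3$power, 9 * t1$power, tolerance = 1e-9)
  d1 <- db_normalize(t1)
  d3 <- db_normalize(t3)
  expect_equal(as.vector(d1), as.vector(d3), tolerance = 1e-8)
})

test_that("dB normalization follows 10*log10(power/baseline)", {
  freqs <- c(2, 4, 8)
  times <- seq(-0.5, 1, by = 0.002)
  nt <- length(times)
  # constant power = baseline -> 0 dB everywhere
  tfr <- structure(list(
    power = array(rep(c(1, 2, 4), each = 2, times = nt),
                  dim = c(2, 3, nt)),
    phase = array(0, dim = c(2, 3, nt)),
    freqs = freqs, times = times, fs = 500), class = "tfr_result")
  db <- db_normalize(tfr)
  expect_equal(max(abs(db)), 0)
  # x10 power after t=0 -> +10 dB
  tfr2 <- tfr
  tfr2$power[, , times > 0] <- tfr2$power[, , times > 0] * 10
  db2 <- db_normalize(tfr2)
  expect_equal(unique(as.vector(round(db2[, times > 0], 10))), 10)
  expect_equal(unique(as.vector(round(db2[, times <= 0], 10))), 0)

  bad <- tfr
  bad$power[] <- 0
  expect_error(db_normalize(bad), "positive")
  expect_error(db_normalize(tfr, baseline = c(5, 6)), "outside")
})

test_that("tf-ROI averaging is inclusive and matches hand arithmetic", {
  m <- matrix(c(0, 2, 4, 6), 2, 2)
  map <- structure(m, freqs = c(1, 4), times = c(0.3, 0.4),
                   class = "tf_map")
  expect_equal(tf_roi_mean(map, roi_delta()), 3)
  cmap <- structure(matrix(1.5, 2, 2), freqs = c(1, 4),
                    times = c(0.3, 0.4), class = "tf_map")
  expect_equal(tf_roi_mean(cmap, roi_delta()), 1.5)
  expect_error(tf_roi_mean(map, roi_spec(c(10, 20), c(0.3, 0.4))),
               "empty")
  # delta and theta ROI presets carry the canonical band/window
  expect_equal(roi_delta()$band, c(1, 4))
  expect_equal(roi_delta()$window, c(0.3, 0.4))
  expect_equal(roi_theta()$band, c(4, 7))
})

test_that("stationary noise yields a near-zero ROI dB", {
  # a single 40-trial ROI estimate scatters with sd ~ 0.15 dB; average a
  # few independent subjects so the check reads the mean, not one draw
  fs <- 500
  bank <- morlet_bank(fs = fs)
  n <- 2.5 * fs
  roi <- withr::with_seed(12, {
    vapply(1:5, function(i) {
      ep <- epoch_set(array(rnorm(40 * n), dim = c(40, 1, n)), fs = fs,
                      t0 = -1, channels = "Cz")
      db <- db_normalize(morlet_tfr(ep, bank, window = c(-0.5, 1)))
      tf_roi_mean(db, roi_delta())
    }, 0)
  })
  expect_lt(abs(mean(roi)), 0.15)
})

test_that("ITPC measures phase clustering and is phase-shift invariant", {
  mk_tfr <- function(phases) {
    nt <- length(phases)
    structure(list(power = array(1, dim = c(nt, 1, 1)),
                   phase = array(phases, dim = c(nt, 1, 1)),
                   freqs = 5, times = 0, fs = 500),
              class = "tfr_result")
  }
  expect_equal(as.vector(itpc(mk_tfr(rep(1.2, 8)))), 1)
  expect_equal(as.vector(itpc(mk_tfr(c(0, pi)))), 0, tolerance = 1e-12)
  expect_error(itpc(mk_tfr(0.4)), "2 trials")

  # Monte-Carlo oracle: E[ITPC] under uniform phases at n=100 ~ 0.089
  withr::with_seed(5, {
    sims <- replicate(400, as.vector(itpc(mk_tfr(runif(100, -pi, pi)))))
  })
  expect_equal(mean(sims), 0.089, tolerance = 0.01)

  withr::with_seed(6, {
    ph <- runif(30, -pi, pi)
  })
  shift <- (ph + 1.1 + pi) %% (2 * pi) - pi
  expect_equal(as.vector(itpc(mk_tfr(ph))),
               as.vector(itpc(mk_tfr(shift))), tolerance = 1e-12)
  expect_true(all(itpc(mk_tfr(ph)) >= 0 & itpc(mk_tfr(ph)) <= 1))
})

test_that("phase-locked bursts raise ITPC at the burst frequency", {
  p <- tiny_profile(n_ctl = 1, n_pd = 0, seed = 30)
  p$phase_locking_frac <- 1
  coh <- simulate_cohort(p)
  coh$latent_gain <- 3
  tr <- simulate_behavior(coh, p, 7, n_trials = 40)
  ep <- simulate_eeg_epochs(coh, tr, p)[[1]]
  bank <- morlet_bank(fs = p$fs)
  tfr <- morlet_tfr(ep, bank, window = c(-0.5, 1))
  pl <- itpc(tfr)
  fi <- which.min(abs(tfr$freqs - p$burst_freq))
  ti_burst <- which.min(abs(tfr$times - p$burst_center))
  ti_pre <- which.min(abs(tfr$times - (-0.3)))
  expect_gt(pl[fi, ti_burst], pl[fi, ti_pre] + 0.3)
})
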