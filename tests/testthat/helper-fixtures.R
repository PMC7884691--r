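# shared fixtures, all generated in code

# a small, fast profile with the default calibration constants
tiny_profile <- function(n_ctl = 4, n_pd = 4, seed = 11) {
  p <- profile_paper_default(seed = seed)
  p$n_control <- n_ctl
  p$n_pd <- n_pd
  p$n_complete <- NULL
  p$n_trials <- 25
  p$epoch_window <- list(`3` = c(-2, 3), `7` = c(-2, 3))
  p
}

# epoch_set with given per-channel constructor f(ch) -> trial x sample matrix
make_epochs <- function(n_trial, n_chan, n_samp, fs = 500, t0 = -0.5,
                        fill = function(ch) matrix(rnorm(n_trial * n_samp),
                                                   n_trial, n_samp)) {
  data <- array(0, dim = c(n_trial, n_chan, n_samp))
  for (ch in seq_len(n_chan)) data[, ch, ] <- fill(ch)
  epoch_set(data, fs = fs, t0 = t0,
            channels = paste0("Ch", seq_len(n_chan)))
}

# subject-level tf maps with an optional rectangular mean shift
make_maps <- function(n_sub, nf, nt, shift = 0, block = NULL, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_sub), function(i) {
      m <- matrix(rnorm(nf * nt), nf, nt)
      if (!is.null(block)) {
        m[block$f, block$t] <- m[block$f, block$t] + shift
      }
      structure(m, freqs = seq_len(nf), times = seq_len(nt) / 100,
                class = "tf_map")
    })
  })
}

# simulate trial data with known fixed effects and random intercepts,
# for LMM parameter-recovery checks
sim_lmm_data <- function(seed, n_sub = 16, n_trial = 40, b_dgm = 0.05) {
  withr::with_seed(seed, {
    subs <- tibble::tibble(
      subject = sprintf("S%02d", seq_len(n_sub)),
      group = rep(c(0, 1), each = n_sub / 2),
      moca = rnorm(n_sub, 0, 3),
      u = rnorm(n_sub, 0, 0.3))
    purrr::pmap_dfr(subs, function(subject, group, moca, u) {
      delta <- rnorm(n_trial, 0, 1)
      interval <- rep(c(3, 7), length.out = n_trial)
      keypress <- 0.9 * interval + u +
        0.05 * delta + b_dgm * delta * group * moca +
        rnorm(n_trial, 0, 0.5)
      tibble::tibble(subject = subject,
                     group = ifelse(group == 1, "PD", "CTL"),
                     moca = moca, delta = delta, interval = interval,
                     keypress = keypress)
    })
  })
}

# direct time-domain convolution oracle: same truncated kernels as the bank,
# centre-aligned analytic signal; O(n * m) via shifted accumulation
direct_morlet <- function(x, bank) {
  n <- length(x)
  out <- matrix(0i, length(bank$freqs), n)
  for (j in seq_along(bank$freqs)) {
    k <- bank$kernels[[j]]
    m <- length(k)
    hw <- (m - 1L) / 2L
    acc <- complex(length.out = n + m - 1L)
    for (i in seq_len(m)) {
      idx <- i:(i + n - 1L)
      acc[idx] <- acc[idx] + k[i] * x
    }
    out[j, ] <- acc[(hw + 1L):(hw + n)]
  }
  out
}
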