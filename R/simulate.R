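#' Simulate a study cohort
#'
#' Draws one subject record per participant: group membership, an integer
#' MOCA score (clipped to 0--30), a motor score (mUPDRS, PD only, clipped to
#' 0--56), a latent timing-variability factor `latent_cv` (group mean 1;
#' tilted by the profile's `cv_moca_link` in PD, multiplicative lognormal
#' subject noise) and a latent burst gain `latent_gain`. Deterministic under
#' a fixed seed.
#'
#' @param profile A [synthetic_profile()].
#' @param seed Seed (defaults to the profile seed).
#' @return A tibble with one row per subject: `id`, `group`, `moca`,
#'   `mupdrs`, `latent_cv`, `latent_gain` and per-interval completion flags.
#' @export
simulate_cohort <- function(profile, seed = profile$seed) {
  validate_profile(profile)
  n_ctl <- as.integer(profile$n_control)
  n_pd <- as.integer(profile$n_pd)
  if (n_ctl < 0 || n_pd < 0) abort("cohort counts must be non-negative.")
  n <- n_ctl + n_pd
  empty <- tibble(id = character(), group = character(),
                  moca = integer(), mupdrs = double(),
                  latent_cv = double(), latent_gain = double())
  if (n == 0L) return(empty)

  withr::with_seed(child_seed(seed, 1L), {
    group <- c(rep("CTL", n_ctl), rep("PD", n_pd))
    id <- c(sprintf("C%03d", seq_len(n_ctl)), sprintf("P%03d", seq_len(n_pd)))
    moca_mean <- setNames(profile$moca$mean, profile$moca$group)
    moca_sd <- setNames(profile$moca$sd, profile$moca$group)
    moca <- as.integer(pmin(30, pmax(0, round(
      rnorm(n, moca_mean[group], moca_sd[group])))))
    mupdrs <- ifelse(group == "PD",
                     pmin(56, pmax(0, round(
                       rnorm(n, profile$mupdrs["mean"],
                             profile$mupdrs["sd"])))),
                     NA_real_)

    # CV--MOCA link, expressed relative to the longest interval's group CV
    ref <- profile$behavior[profile$behavior$interval ==
                              max(profile$behavior$interval), ]
    ref_cv <- setNames(ref$sd_keypress / ref$mean_keypress, ref$group)
    centred <- moca - moca_mean[group]
    tilt <- ifelse(group == "PD",
                   1 + (profile$cv_moca_link / ref_cv["PD"]) * centred, 1)
    sdl <- profile$cv_subject_sdlog
    latent_cv <- pmax(0.1, tilt) * rlnorm(n, -sdl^2 / 2, sdl)

    gain0 <- profile$burst_gain[group]
    gsd <- profile$burst_gain_sdlog
    latent_gain <- pmax(0, gain0 *
                          pmax(0, 1 + profile$burst_moca_link * centred) *
                          rlnorm(n, -gsd^2 / 2, gsd))

    out <- tibble(id = id, group = group, moca = moca, mupdrs = mupdrs,
                  latent_cv = latent_cv, latent_gain = latent_gain)
    # per-interval task completion (emulates real-world attrition)
    for (iv in names(profile$epoch_window)) {
      col <- paste0("complete_", iv)
      if (is.null(profile$n_complete[[iv]])) {
        out[[col]] <- TRUE
      } else {
        want <- profile$n_complete[[iv]]
        done <- logical(n)
        for (g in c("CTL", "PD")) {
          idx <- which(group == g)
          k <- min(length(idx), want[[g]] %||% length(idx))
          done[sample(idx, k)] <- TRUE
        }
        out[[col]] <- done
      }
    }
    out
  })
}

#' Simulate interval-timing behavior
#'
#' Per subject and trial, the keypress time is drawn from a normal
#' distribution with the profile's group/interval mean and a subject-specific
#' standard deviation `latent_cv * sd_keypress(group, interval)`, truncated
#' below at 0.2 s (nonphysical earlier presses are redrawn). Trials come in
#' blocks of 20, matching the task structure.
#'
#' @param subjects Cohort tibble from [simulate_cohort()].
#' @param profile The [synthetic_profile()] used to generate the cohort.
#' @param interval Interval in seconds (3 or 7).
#' @param n_trials Trials per completing subject (default: profile value);
#'   subjects not completing this interval get `profile$n_trials_incomplete`.
#' @param seed Seed (defaults to the profile seed).
#' @return A tibble of trial records: `subject`, `group`, `interval`,
#'   `block`, `trial`, `keypress` (seconds).
#' @export
simulate_behavior <- function(subjects, profile, interval,
                              n_trials = NULL, seed = profile$seed) {
  if (!interval %in% profile$behavior$interval) {
    abort(sprintf("unknown interval %s: profile defines %s s.", interval,
                  paste(unique(profile$behavior$interval), collapse = ", ")))
  }
  n_trials <- n_trials %||% profile$n_trials
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  if (nrow(subjects) == 0L) {
    return(tibble(subject = character(), group = character(),
                  interval = double(), block = integer(), trial = integer(),
                  keypress = double()))
  }
  beh <- profile$behavior[profile$behavior$interval == interval, ]
  mu <- setNames(beh$mean_keypress, beh$group)
  sd0 <- setNames(beh$sd_keypress, beh$group)
  ccol <- paste0("complete_", interval)
  complete <- if (ccol %in% names(subjects)) subjects[[ccol]] else TRUE
  nt <- ifelse(rep(complete, length.out = nrow(subjects)),
               n_trials, profile$n_trials_incomplete)

  withr::with_seed(child_seed(seed, 2L + interval), {
    purrr::pmap_dfr(
      list(subjects$id, subjects$group, subjects$latent_cv, nt),
      function(id, g, lcv, k) {
        s <- lcv * sd0[[g]]
        r <- rnorm(k, mu[[g]], s)
        while (any(r <= 0.2)) {                # truncate: redraw early presses
          bad <- r <= 0.2
          r[bad] <- rnorm(sum(bad), mu[[g]], s)
        }
        tibble(subject = id, group = g, interval = interval,
               block = as.integer(ceiling(seq_len(k) / 20)),
               trial = seq_len(k), keypress = r)
      })
  })
}

# 1/f ("pink") background noise, one column per trial, exact RMS scaling.
# Frequency-domain shaping of white noise: |H(f)| ~ f^(-1/2) so power ~ 1/f.
pink_noise <- function(n, n_trials, fs, rms) {
  white <- matrix(rnorm(n * n_trials), nrow = n)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * fs / n
  h <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(mvfft(mvfft(white) * h, inverse = TRUE)) / n
  sds <- apply(x, 2, sd)
  sweep(x, 2, rms / sds, `*`)
}

#' Simulate cue-locked EEG epochs
#'
#' Each trial is 1/f background noise plus a Gaussian-windowed sinusoidal
#' burst (see [synthetic_profile()]). The trial burst gain is the subject's
#' `latent_gain` jittered trial-to-trial and negatively correlated (strength
#' `trial_coupling`) with the trial's absolute keypress error, so precise
#' trials carry stronger bursts. A fraction `phase_locking_frac` of trials
#' share a fixed carrier phase at the burst centre; the rest are uniform.
#' The burst is injected at channel "Cz" (or the first channel).
#'
#' @param subjects Cohort tibble from [simulate_cohort()].
#' @param trials Trial tibble from [simulate_behavior()]; must contain a
#'   single interval and only subjects present in `subjects`.
#' @param profile The [synthetic_profile()].
#' @param seed Seed (defaults to the profile seed).
#' @param window Optional `c(t0, t1)` epoch window override (seconds,
#'   cue-locked); defaults to the profile's window for the interval.
#' @return A named list of [epoch_set()] objects, one per subject appearing
#'   in `trials` (trial order matches the subject's rows in `trials`).
#' @export
simulate_eeg_epochs <- function(subjects, trials, profile,
                                seed = profile$seed, window = NULL) {
  iv <- unique(trials$interval)
  if (length(iv) != 1L) {
    abort("`trials` must contain a single interval; split by interval first.")
  }
  if (!all(trials$subject %in% subjects$id)) {
    abort("mismatched ids: `trials` references subjects not in `subjects`.")
  }
  if (profile$fs <= 2 * profile$burst_freq) {
    abort("fs must exceed twice the burst frequency.")
  }
  window <- window %||% profile$epoch_window[[as.character(iv)]]
  if (is.null(window)) abort("profile has no epoch window for this interval.")
  fs <- profile$fs
  n <- as.integer(round((window[2] - window[1]) * fs))
  tax <- window[1] + (seq_len(n) - 1) / fs
  chans <- profile$channels
  burst_ch <- if ("Cz" %in% chans) which(chans == "Cz") else 1L
  envelope <- exp(-(tax - profile$burst_center)^2 /
                    (2 * profile$burst_width^2))

  subj_ids <- unique(trials$subject)
  out <- vector("list", length(subj_ids))
  names(out) <- subj_ids
  withr::with_seed(child_seed(seed, 20L + iv), {
    for (si in seq_along(subj_ids)) {
      id <- subj_ids[si]
      sub <- subjects[subjects$id == id, ]
      tr <- trials[trials$subject == id, ]
      k <- nrow(tr)

      err <- abs(tr$keypress - iv)
      z <- if (k > 1L && sd(err) > 0) (err - mean(err)) / sd(err) else
        rep(0, k)
      rho <- profile$trial_coupling
      jit <- profile$trial_gain_jitter
      gain <- sub$latent_gain *
        pmax(0, 1 + jit * (-rho * z + sqrt(1 - rho^2) * rnorm(k)))

      locked <- runif(k) < profile$phase_locking_frac
      phase <- ifelse(locked, 0, runif(k, -pi, pi))

      data <- array(0, dim = c(k, length(chans), n))
      for (ch in seq_along(chans)) {
        data[, ch, ] <- t(pink_noise(n, k, fs, profile$noise_rms))
      }
      if (any(gain > 0)) {
        carrier <- 2 * pi * profile$burst_freq * (tax - profile$burst_center)
        burst <- (gain * profile$noise_rms) *
          t(vapply(seq_len(k),
                   function(i) envelope * cos(carrier + phase[i]),
                   numeric(n)))
        data[, burst_ch, ] <- data[, burst_ch, ] + burst
      }
      out[[si]] <- epoch_set(data, fs = fs, t0 = window[1],
                             channels = chans, alignment = "cue",
                             interval = iv, subject = id)
    }
  })
  out
}
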