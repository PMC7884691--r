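#' Complex Morlet wavelet bank
#'
#' The bank is 50 frequencies log-spaced from 1 to 50 Hz with cycle counts
#' increasing linearly over the frequency index from 3 to 10. Each wavelet
#' is a Gaussian-windowed complex sine, `exp(i 2 pi f t) exp(-t^2/(2 s^2))`
#' with `s = cycles / (2 pi f)`, sampled over +/- 4 s and normalized so a
#' unit-amplitude sinusoid at the wavelet's frequency yields an analytic
#' signal of magnitude ~1.
#'
#' @param n_freq Number of frequencies (default 50).
#' @param f_range Frequency range in Hz (default `c(1, 50)`).
#' @param cycle_range Cycle range across the bank (default `c(3, 10)`).
#' @param fs Sampling rate, Hz.
#' @return An object of class `morlet_bank`: `freqs`, `cycles`, `sigma`
#'   (seconds), `fs`, and the sampled `kernels` (list of complex vectors).
#' @export
morlet_bank <- function(n_freq = 50, f_range = c(1, 50),
                        cycle_range = c(3, 10), fs = 500) {
  if (fs <= 2 * f_range[2]) {
    abort("sampling rate too low for the requested maximum frequency.")
  }
  freqs <- 10^seq(log10(f_range[1]), log10(f_range[2]), length.out = n_freq)
  cycles <- seq(cycle_range[1], cycle_range[2], length.out = n_freq)
  sigma <- cycles / (2 * pi * freqs)
  kernels <- lapply(seq_len(n_freq), function(j) {
    hw <- ceiling(4 * sigma[j] * fs)
    tk <- (-hw:hw) / fs
    env <- exp(-tk^2 / (2 * sigma[j]^2))
    # peak spectral gain 2: the one-sided wavelet then returns magnitude
    # ~A for a real sinusoid of amplitude A (analytic-signal convention)
    (2 * env / sum(env)) * exp(2i * pi * freqs[j] * tk)
  })
  structure(list(freqs = freqs, cycles = cycles, sigma = sigma, fs = fs,
                 kernels = kernels),
            class = "morlet_bank")
}

#' @export
print.morlet_bank <- function(x, ...) {
  cat(sprintf("<morlet_bank> %d freqs %.3g-%.3g Hz, %g-%g cycles, fs %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              min(x$cycles), max(x$cycles), x$fs))
  invisible(x)
}

#' Morlet time-frequency decomposition
#'
#' Convolves every trial of one channel with the wavelet bank by spectral
#' multiplication: the FFT of the zero-padded trial is multiplied with the
#' FFT of each zero-padded wavelet and inverse-transformed, which is
#' identical to direct time-domain convolution. Power is the squared
#' magnitude and phase the argument of the resulting analytic signal.
#'
#' Epochs should extend beyond any window that is later analysed: the
#' lowest-frequency wavelets span roughly +/- 3 sigma (about +/- 1.4 s at
#' 1 Hz / 3 cycles), and power inside that margin of the epoch edges is
#' attenuated by the zero padding.
#'
#' @param epochs An [epoch_set()].
#' @param bank A [morlet_bank()] (must match the epoch sampling rate).
#' @param channel Channel label or index to decompose (default "Cz").
#' @param window Optional `c(tmin, tmax)` (seconds) to crop the output time
#'   axis, keeping memory bounded for long epochs.
#' @return An object of class `tfr_result`: arrays `power` and `phase` of
#'   dimension `(trial, frequency, time)`, plus `freqs`, `times`, `fs`.
#' @export
morlet_tfr <- function(epochs, bank, channel = "Cz", window = NULL) {
  if (!inherits(bank, "morlet_bank")) abort("`bank` must be a morlet_bank.")
  if (bank$fs != epochs$fs) abort("bank and epochs disagree on fs.")
  if (is.character(channel)) {
    ch <- match(channel, epochs$channels)
    if (is.na(ch)) abort(sprintf("channel '%s' not present.", channel))
  } else ch <- as.integer(channel)
  x <- epochs$data[, ch, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_trial <- nrow(x)
  n <- ncol(x)
  times <- epoch_times(epochs)
  keep <- if (is.null(window)) seq_len(n) else
    axis_window(times, window[1], window[2])
  if (length(keep) == 0L) abort("crop window outside the epoch.")

  hw_max <- (max(lengths(bank$kernels)) - 1L) / 2L
  nfft <- nextn(n + 2L * hw_max, 2)
  X <- mvfft(rbind(t(x), matrix(0, nfft - n, n_trial)))

  nf <- length(bank$freqs)
  nt <- length(keep)
  power <- array(0, dim = c(n_trial, nf, nt))
  phase <- array(0, dim = c(n_trial, nf, nt))
  for (j in seq_len(nf)) {
    k <- bank$kernels[[j]]
    hw <- (length(k) - 1L) / 2L
    K <- fft(c(k, rep(0, nfft - length(k))))
    A <- mvfft(X * K, inverse = TRUE) / nfft     # full linear convolution
    A <- A[hw + keep, , drop = FALSE]            # centre-aligned, cropped
    power[, j, ] <- t(Mod(A)^2)
    phase[, j, ] <- t(Arg(A))
  }
  structure(list(power = power, phase = phase, freqs = bank$freqs,
                 times = times[keep], fs = epochs$fs,
                 subject = epochs$subject, interval = epochs$interval),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr_result> %d trials x %d freqs x %d samples, t = %.3g..%.3g s\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Decibel baseline normalization
#'
#' Trial-averaged power at every (frequency, time) pixel is divided by the
#' mean pre-event baseline power at the same frequency and converted to
#' decibels: `10 * log10(power / baseline)`. The baseline is the mean of
#' trial-averaged power over the baseline window (default -300..-200 ms
#' before the event), computed per frequency.
#'
#' @param tfr A [morlet_tfr()] result.
#' @param baseline `c(lo, hi)` baseline window in seconds (both ends
#'   inclusive on the sample grid).
#' @return A `tf_map`: matrix `frequency x time` of dB values with
#'   attributes `freqs`, `times`, `baseline` (the per-frequency baseline
#'   power).
#' @export
db_normalize <- function(tfr, baseline = c(-0.3, -0.2)) {
  idx <- axis_window(tfr$times, baseline[1], baseline[2])
  if (length(idx) == 0L) abort("baseline window outside the epoch.")
  pbar <- apply(tfr$power, c(2, 3), mean)            # freq x time
  b <- rowMeans(pbar[, idx, drop = FALSE])
  if (any(b <= 0)) abort("baseline power must be positive.")
  structure(10 * log10(pbar / b),
            freqs = tfr$freqs, times = tfr$times, baseline = b,
            class = "tf_map")
}

#' Per-trial dB power
#'
#' Like [db_normalize()] but keeps the trial dimension: each trial's power
#' is normalized by the condition-average baseline (the same per-frequency
#' baseline as the trial-averaged map), yielding single-trial dB values for
#' trial-wise modeling.
#'
#' @inheritParams db_normalize
#' @return Array `(trial, frequency, time)` of dB values with `freqs` /
#'   `times` attributes.
#' @export
db_normalize_trials <- function(tfr, baseline = c(-0.3, -0.2)) {
  idx <- axis_window(tfr$times, baseline[1], baseline[2])
  if (length(idx) == 0L) abort("baseline window outside the epoch.")
  b <- rowMeans(apply(tfr$power, c(2, 3), mean)[, idx, drop = FALSE])
  if (any(b <= 0)) abort("baseline power must be positive.")
  db <- 10 * log10(sweep(tfr$power, 2, b, `/`))
  attr(db, "freqs") <- tfr$freqs
  attr(db, "times") <- tfr$times
  db
}

#' Rectangular time-frequency region of interest
#'
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param window `c(t_lo, t_hi)` in seconds relative to the event.
#' @return A `roi_spec` list. Presets: `roi_delta()` (1--4 Hz),
#'   `roi_theta()` (4--7 Hz), both over the canonical 300--400 ms post-cue
#'   window.
#' @export
roi_spec <- function(band, window) {
  if (band[1] >= band[2]) abort("roi band bounds reversed.")
  if (window[1] >= window[2]) abort("roi window bounds reversed.")
  structure(list(band = band, window = window), class = "roi_spec")
}

#' @rdname roi_spec
#' @export
roi_delta <- function() roi_spec(c(1, 4), c(0.3, 0.4))

#' @rdname roi_spec
#' @export
roi_theta <- function() roi_spec(c(4, 7), c(0.3, 0.4))

#' Mean dB over a tf-ROI
#'
#' Averages the dB map over all pixels with frequency in `band` and time in
#' `window`, both ends inclusive on the map's grid.
#'
#' @param db_map A `tf_map` from [db_normalize()].
#' @param roi A [roi_spec()].
#' @return A single dB value.
#' @export
tf_roi_mean <- function(db_map, roi) {
  fi <- axis_window(attr(db_map, "freqs"), roi$band[1], roi$band[2])
  ti <- axis_window(attr(db_map, "times"), roi$window[1], roi$window[2])
  if (length(fi) == 0L || length(ti) == 0L) abort("empty tf-ROI.")
  mean(db_map[fi, ti])
}

#' Per-trial tf-ROI dB values
#'
#' Single-trial mean dB over the ROI, using the condition-average baseline
#' (see [db_normalize_trials()]); the input to trial-wise models.
#'
#' @param tfr A [morlet_tfr()] result.
#' @param roi A [roi_spec()].
#' @param baseline Baseline window in seconds.
#' @return Numeric vector, one dB value per trial.
#' @export
tf_roi_trials <- function(tfr, roi, baseline = c(-0.3, -0.2)) {
  db <- db_normalize_trials(tfr, baseline)
  fi <- axis_window(tfr$freqs, roi$band[1], roi$band[2])
  ti <- axis_window(tfr$times, roi$window[1], roi$window[2])
  if (length(fi) == 0L || length(ti) == 0L) abort("empty tf-ROI.")
  apply(db[, fi, ti, drop = FALSE], 1, mean)
}

#' Inter-trial phase clustering
#'
#' The magnitude of the trial-average unit phasor at every (frequency, time)
#' pixel: 1 when all trials share a phase, near 0 for uniform phases
#' (expectation ~ sqrt(pi)/(2 sqrt(n)) under the null).
#'
#' @param tfr A [morlet_tfr()] result with at least 2 trials.
#' @return A `tf_map` of ITPC values in `[0, 1]`.
#' @export
itpc <- function(tfr) {
  if (dim(tfr$phase)[1] < 2L) abort("ITPC needs at least 2 trials.")
  m <- apply(exp(1i * tfr$phase), c(2, 3), mean)
  structure(Mod(m), freqs = tfr$freqs, times = tfr$times,
            class = "tf_map")
}
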