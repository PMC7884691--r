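#' Trial-averaged, low-pass-filtered ERP
#'
#' Averages epochs over trials at one channel and applies a zero-phase
#' (forward-backward) 4th-order Butterworth low-pass at `cutoff_hz`
#' (default 20 Hz).
#'
#' @param epochs An [epoch_set()].
#' @param channel Channel label or index (default "Cz").
#' @param cutoff_hz Low-pass cutoff, Hz; must be below Nyquist.
#' @return An `erp_waveform`: tibble with columns `time` (s) and
#'   `amplitude` (microvolts); attributes `fs`, `n_trials`, `alignment`.
#' @export
erp_average <- function(epochs, channel = "Cz", cutoff_hz = 20) {
  if (cutoff_hz >= epochs$fs / 2) abort("cutoff must be below Nyquist.")
  if (is.character(channel)) {
    ch <- match(channel, epochs$channels)
    if (is.na(ch)) abort(sprintf("channel '%s' not present.", channel))
  } else ch <- as.integer(channel)
  x <- epochs$data[, ch, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  avg <- colMeans(x)
  bf <- signal::butter(4, cutoff_hz / (epochs$fs / 2), type = "low")
  # odd-reflection padding suppresses forward-backward edge transients
  n <- length(avg)
  np <- min(n - 1L, as.integer(epochs$fs))
  padded <- c(2 * avg[1] - avg[(np + 1):2], avg,
              2 * avg[n] - avg[(n - 1):(n - np)])
  filt <- signal::filtfilt(bf, padded)[(np + 1):(np + n)]
  structure(tibble(time = epoch_times(epochs), amplitude = filt),
            fs = epochs$fs, n_trials = nrow(x), alignment = epochs$alignment,
            class = c("erp_waveform", "tbl_df", "tbl", "data.frame"))
}

#' Peak-to-trough component amplitude
#'
#' The canonical morphological ERP measure: the maximum amplitude inside
#' the peak search window minus the minimum inside the trough window.
#' Default windows (documented configuration choices, e.g. cue-locked
#' P2 at 150--300 ms and N2 at 200--350 ms) live with the caller.
#'
#' @param erp An `erp_waveform` from [erp_average()].
#' @param peak_window,trough_window `c(lo, hi)` in seconds.
#' @param component Label for the feature row.
#' @return A tibble row: `component`, `value` (microvolts), window bounds.
#' @export
peak_to_trough <- function(erp, peak_window, trough_window,
                           component = "P2-N2") {
  pi_ <- axis_window(erp$time, peak_window[1], peak_window[2])
  ti_ <- axis_window(erp$time, trough_window[1], trough_window[2])
  if (length(pi_) == 0L || length(ti_) == 0L) {
    abort("empty search window.")
  }
  tibble(component = component,
         value = max(erp$amplitude[pi_]) - min(erp$amplitude[ti_]),
         peak_lo = peak_window[1], peak_hi = peak_window[2],
         trough_lo = trough_window[1], trough_hi = trough_window[2])
}

#' Contingent negative variation amplitude
#'
#' Mean amplitude of the cue-locked ERP over 500--3000 ms for the 3-s
#' interval or 500--7000 ms for the 7-s interval: the slow anticipatory
#' potential between the imperative cue and the target time.
#'
#' @param erp An `erp_waveform`.
#' @param interval Interval condition, 3 or 7 (seconds).
#' @return A tibble row: `component` ("CNV3"/"CNV7"), `value`, window.
#' @export
cnv_amplitude <- function(erp, interval) {
  win <- switch(as.character(interval),
                `3` = c(0.5, 3), `7` = c(0.5, 7),
                abort("unknown interval: CNV is defined for 3 or 7 s."))
  idx <- axis_window(erp$time, win[1], win[2])
  if (length(idx) == 0L) abort("epoch does not cover the CNV window.")
  tibble(component = paste0("CNV", interval),
         value = mean(erp$amplitude[idx]),
         window_lo = win[1], window_hi = win[2])
}
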