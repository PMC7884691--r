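#' Epoch containers
#'
#' An `epoch_set` holds event-locked EEG segments as a
#' `trial x channel x sample` numeric array (microvolts) together with its
#' sampling rate, the time of the first sample relative to the alignment
#' event, channel labels, the alignment event ("cue" or "response") and the
#' interval condition the trials belong to.
#'
#' @param data Numeric array `(trial, channel, sample)`.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample relative to the event, seconds.
#' @param channels Character vector of channel labels.
#' @param alignment "cue" or "response".
#' @param interval Interval condition in seconds (3 or 7), or `NA`.
#' @param subject Optional subject id the epochs belong to.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, channels, alignment = "cue",
                      interval = NA_real_, subject = NA_character_) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a trial x channel x sample array.")
  }
  if (dim(data)[2] != length(channels)) {
    abort("number of channel labels must match dim(data)[2].")
  }
  if (!all(is.finite(data))) abort("epoch data must be finite.")
  alignment <- match.arg(alignment, c("cue", "response"))
  structure(list(data = data, fs = fs, t0 = t0, channels = channels,
                 alignment = alignment, interval = interval,
                 subject = subject),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set%s> %d trials x %d channels x %d samples, fs = %g Hz, t = %g..%g s (%s-locked)\n",
    if (is.na(x$subject)) "" else paste0(" ", x$subject),
    d[1], d[2], d[3], x$fs, x$t0, x$t0 + (d[3] - 1) / x$fs, x$alignment))
  invisible(x)
}

#' Time axis of an epoch set
#' @param epochs An `epoch_set`.
#' @return Numeric vector of sample times (seconds, event at 0).
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs
}

#' Cut event-locked epochs from a continuous recording
#'
#' Extracts windows `[t0, t1)` around each event. The sample count is
#' `round((t1 - t0) * fs)`; for a 7-s-interval cue window of -2..+20 s at
#' 500 Hz that is 11000 samples. Events whose window would leave the
#' recording are dropped with a warning reporting the count.
#'
#' @param raw Numeric matrix `channel x sample` (continuous recording).
#' @param events Event times in seconds from recording start.
#' @param t0,t1 Window relative to each event, seconds (`t0 < t1`).
#' @param fs Sampling rate, Hz.
#' @param channels Channel labels (defaults to rownames or Ch1..ChN).
#' @inheritParams epoch_set
#' @return An `epoch_set`.
#' @export
epoch <- function(raw, events, t0, t1, fs, channels = NULL,
                  alignment = "cue", interval = NA_real_) {
  if (!is.matrix(raw)) abort("`raw` must be a channel x sample matrix.")
  if (t1 <= t0) abort("`t0` must precede `t1`.")
  channels <- channels %||% rownames(raw) %||%
    paste0("Ch", seq_len(nrow(raw)))
  n <- as.integer(round((t1 - t0) * fs))
  starts <- as.integer(round((events + t0) * fs)) + 1L
  ok <- starts >= 1L & (starts + n - 1L) <= ncol(raw)
  if (any(!ok)) {
    warn(sprintf("%d of %d events dropped: window outside recording.",
                 sum(!ok), length(events)))
  }
  starts <- starts[ok]
  if (length(starts) == 0L) abort("no events with a complete window.")
  data <- array(0, dim = c(length(starts), nrow(raw), n))
  for (i in seq_along(starts)) {
    data[i, , ] <- raw[, starts[i]:(starts[i] + n - 1L), drop = FALSE]
  }
  epoch_set(data, fs = fs, t0 = t0, channels = channels,
            alignment = alignment, interval = interval)
}

#' Re-reference epochs to the channel average
#'
#' Subtracts, at every trial and sample, the mean across channels, so the
#' channel mean is zero everywhere (the "average reference"). Requires at
#' least two channels.
#'
#' @param epochs An `epoch_set`.
#' @return The re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  d <- dim(epochs$data)
  if (d[2] < 2L) abort("average reference needs at least 2 channels.")
  m <- apply(epochs$data, c(1, 3), mean)     # trial x sample
  epochs$data <- epochs$data -
    aperm(array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Flag and repair outlier channels
#'
#' A simplified robust detector in the spirit of automated EEG
#' quality-control pipelines: a channel is flagged when the robust z-score
#' (median/MAD) of its pooled log-variance exceeds `z_thresh` in magnitude
#' (catching both noisy and dead channels), or when the robust z-score of
#' its mean correlation with the other channels falls below `-z_thresh`.
#' Because robust z-scores diverge when all channels are nearly identical,
#' a flag additionally requires a material absolute deviation: a variance
#' ratio of at least 2 against the median, or a mean-correlation drop of at
#' least 0.1. Flagged channels are replaced by the mean of the unflagged
#' channels.
#'
#' @param epochs An `epoch_set` with at least 8 channels.
#' @param z_thresh Robust z threshold (default 3).
#' @return A list: `epochs` (repaired), `flagged` (labels), `stats`
#'   (per-channel tibble of the two z-scores).
#' @export
detect_bad_channels <- function(epochs, z_thresh = 3) {
  d <- dim(epochs$data)
  if (d[2] < 8L) abort("robust channel statistics need >= 8 channels.")
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])  # chan x (trial*sample)
  lv <- log(pmax(apply(flat, 1, var), .Machine$double.xmin))
  live <- apply(flat, 1, sd) > 0
  mc <- rep(0, d[2])                      # dead channels: correlation 0
  if (sum(live) >= 2) {
    cc <- cor(t(flat[live, , drop = FALSE]))
    diag(cc) <- NA
    mc[live] <- rowMeans(cc, na.rm = TRUE)
  }
  rz <- function(x) {
    s <- mad(x)
    if (!is.finite(s) || s == 0) s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - median(x)) / s
  }
  z_var <- rz(lv)
  z_cor <- rz(mc)
  # robust z alone explodes for near-identical channels; require a
  # material absolute deviation as well
  bad <- (abs(z_var) > z_thresh & abs(lv - median(lv)) > log(2)) |
    (z_cor < -z_thresh & (median(mc) - mc) > 0.1)
  if (mean(bad) > 0.25) {
    warn(sprintf("%d of %d channels flagged (> 25%%); proceeding.",
                 sum(bad), d[2]))
  }
  if (any(bad) && any(!bad)) {
    good_mean <- apply(epochs$data[, !bad, , drop = FALSE], c(1, 3), mean)
    for (ch in which(bad)) epochs$data[, ch, ] <- good_mean
  }
  list(epochs = epochs,
       flagged = epochs$channels[bad],
       stats = tibble(channel = epochs$channels, log_variance = lv,
                      mean_correlation = mc, z_variance = z_var,
                      z_correlation = z_cor, flagged = bad))
}

#' Write / read an epoch directory container
#'
#' Epoch data are stored as raw little-endian float32 binary (one file per
#' epoch set) next to a human-readable YAML sidecar holding the sampling
#' rate, window start, array shape, channel labels, alignment and interval.
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory to write into (created if needed).
#' @param name File stem (defaults to the subject id or "epochs").
#' @return `write_epochs()` returns the data-file path invisibly;
#'   `read_epochs()` returns an `epoch_set`.
#' @export
write_epochs <- function(epochs, dir, name = NULL) {
  name <- name %||% (if (is.na(epochs$subject)) "epochs" else epochs$subject)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bin <- file.path(dir, paste0(name, ".f32"))
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4L, endian = "little")
  yaml::write_yaml(
    list(fs = epochs$fs, t0 = epochs$t0, shape = dim(epochs$data),
         channels = as.list(epochs$channels), alignment = epochs$alignment,
         interval = epochs$interval, subject = epochs$subject,
         dtype = "float32-le", order = "sample-channel-trial"),
    file.path(dir, paste0(name, ".yaml")))
  invisible(bin)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir, name) {
  meta <- yaml::read_yaml(file.path(dir, paste0(name, ".yaml")))
  shape <- as.integer(unlist(meta$shape))
  con <- file(file.path(dir, paste0(name, ".f32")), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = prod(shape), size = 4L,
               endian = "little")
  epoch_set(aperm(array(x, dim = rev(shape)), c(3, 2, 1)),
            fs = meta$fs, t0 = meta$t0,
            channels = unlist(meta$channels), alignment = meta$alignment,
            interval = if (is.null(meta$interval)) NA_real_ else meta$interval,
            subject = meta$subject %||% NA_character_)
}
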