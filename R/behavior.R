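#' Per-subject keypress summaries
#'
#' For every (subject, interval) cell, computes the number of trials, the
#' mean keypress time, the sample standard deviation (n-1 denominator) and
#' the coefficient of variation CV = sd / mean, the task's unit-free
#' precision metric. Cells with fewer than two trials have no defined sd;
#' they are kept but flagged, with `sd_keypress` and `cv` set to `NA`.
#'
#' @param trials Trial tibble with columns `subject`, `interval`,
#'   `keypress` (and optionally `group`, carried through).
#' @return A tibble with one row per (subject, interval): `n_trials`,
#'   `mean_keypress`, `sd_keypress`, `cv`, `flagged`.
#' @export
keypress_summary <- function(trials) {
  if (!all(c("subject", "interval", "keypress") %in% names(trials))) {
    abort("`trials` needs columns subject, interval, keypress.")
  }
  keys <- intersect(c("subject", "group", "interval"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_keypress = mean(.data$keypress),
      sd_keypress = if (dplyr::n() >= 2) sd(.data$keypress) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(cv = .data$sd_keypress / .data$mean_keypress,
                  flagged = .data$n_trials < 2)
}

#' Trial-count inclusion filter
#'
#' Retains only cells with at least `min_trials` trials. With the default
#' `min_trials = 21`, a subject is kept only with strictly more than 20
#' trials of the interval, the study's inclusion rule.
#'
#' @param summaries Output of [keypress_summary()].
#' @param min_trials Minimum trial count to retain (default 21).
#' @return The retained rows of `summaries`.
#' @export
filter_subjects <- function(summaries, min_trials = 21) {
  if (min_trials < 1) abort("`min_trials` must be >= 1.")
  dplyr::filter(summaries, .data$n_trials >= min_trials)
}

#' Gaussian-kernel density of keypress times
#'
#' Density summaries of the keypress distribution (used for figures only;
#' no statistic reads them). Bandwidth defaults to Silverman's rule of
#' thumb.
#'
#' @param trials Trial tibble (or any data frame with a `keypress` column).
#' @param bandwidth Kernel bandwidth in seconds, or `NULL` for Silverman.
#' @param n Grid size.
#' @return A tibble with columns `time` and `density`; the curve integrates
#'   to ~1 over the evaluated grid.
#' @export
keypress_density <- function(trials, bandwidth = NULL, n = 512) {
  x <- trials$keypress
  if (length(x) < 2) abort("density needs at least 2 trials.")
  if (!is.null(bandwidth) && bandwidth <= 0) {
    abort("`bandwidth` must be positive.")
  }
  d <- density(x, bw = bandwidth %||% "nrd0", kernel = "gaussian", n = n)
  tibble(time = d$x, density = d$y)
}
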