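#' Plot a time-frequency map
#'
#' Raster of a dB (or ITPC) map with a log-scaled frequency axis,
#' optionally outlining a tf-ROI.
#'
#' @param object A `tf_map` from [db_normalize()] or [itpc()].
#' @param roi Optional [roi_spec()] to outline.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_map <- function(object, roi = NULL, ...) {
  df <- tidyr::expand_grid(freq = attr(object, "freqs"),
                           time = attr(object, "times"))
  df$value <- as.vector(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "time from event (s)", y = "frequency (Hz)",
                  fill = "dB")
  if (!is.null(roi)) {
    p <- p + ggplot2::annotate("rect", xmin = roi$window[1],
                               xmax = roi$window[2], ymin = roi$band[1],
                               ymax = roi$band[2], fill = NA,
                               colour = "black")
  }
  p
}

#' @export
autoplot.erp_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event (s)", y = "amplitude (µV)")
}

#' Keypress density figure
#'
#' Density estimates of keypress times by group, the standard behavioral
#' summary figure for a time-production task.
#'
#' @param trials Trial tibble with `keypress` and `group` columns.
#' @param target Optional target interval (seconds) drawn as a reference.
#' @return A ggplot.
#' @export
plot_keypress_density <- function(trials, target = NULL) {
  p <- ggplot2::ggplot(trials, ggplot2::aes(.data$keypress,
                                            colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "keypress time (s)", y = "density")
  if (!is.null(target)) {
    p <- p + ggplot2::geom_vline(xintercept = target, linetype = 2)
  }
  p
}

#' Per-subject slope figure
#'
#' Plots each subject's trial-wise slope of keypress on delta power as a
#' line over the observed power range, split by group.
#'
#' @param slopes Output of [subject_slopes()].
#' @param data The trial-level data the slopes were fitted on.
#' @return A ggplot.
#' @export
plot_subject_slopes <- function(slopes, data) {
  rng <- range(data$delta, na.rm = TRUE)
  mu <- dplyr::group_by(data, .data$subject) |>
    dplyr::summarise(mk = mean(.data$keypress), md = mean(.data$delta))
  df <- dplyr::inner_join(dplyr::filter(slopes, !is.na(.data$slope)), mu,
                          by = "subject") |>
    dplyr::mutate(x0 = rng[1], x1 = rng[2],
                  y0 = .data$mk + .data$slope * (rng[1] - .data$md),
                  y1 = .data$mk + .data$slope * (rng[2] - .data$md))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$y0, yend = .data$y1,
                                       colour = .data$group),
                          alpha = 0.6) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "cue-evoked delta power (dB)",
                  y = "keypress time (s)")
}
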