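# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Quadrant scatter of waveform shape
#'
#' Peak-to-trough ratio against rise-to-fall ratio, one point per
#' channel/recording, with the quadrant axes drawn. Q4 (lower right:
#' positive peak-to-trough, negative rise-to-fall) is the canonical
#' sensorimotor shape - sharper peaks with steeper decays.
#'
#' @param metrics a tibble containing `peak_trough_ratio` and
#'   `rise_fall_ratio` (e.g. from [analyze_cohort()]).
#' @param colour optional column (tidy-eval) mapped to point colour, e.g.
#'   `pac` or `condition`.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(metrics, colour = NULL) {
  p <- ggplot2::ggplot(metrics,
                       ggplot2::aes(x = .data$rise_fall_ratio,
                                    y = .data$peak_trough_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Rise-to-fall ratio", y = "Peak-to-trough ratio")
  col <- rlang::enquo(colour)
  if (!rlang::quo_is_null(col)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = !!col))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Plot a signal excerpt with its detected cycle landmarks
#'
#' @param x raw signal.
#' @param fs sampling rate in Hz.
#' @param cycles tibble from [cycle_features()].
#' @param t_range time window to display, in seconds.
#' @return A ggplot object.
#' @export
plot_cycle_features <- function(x, fs, cycles, t_range = c(0, 1)) {
  idx <- seq.int(max(1L, floor(t_range[1] * fs) + 1L),
                 min(length(x), ceiling(t_range[2] * fs)))
  sig <- tibble(t = (idx - 1) / fs, x = x[idx])
  pts <- dplyr::bind_rows(
    tibble(i = cycles$peak_idx, what = "peak"),
    tibble(i = cycles$trough_idx, what = "trough")
  ) |>
    dplyr::filter(!is.na(.data$i), .data$i %in% idx) |>
    dplyr::mutate(t = (.data$i - 1) / fs, x = x[.data$i])
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(colour = .data$what), size = 2) +
    ggplot2::labs(x = "Time (s)", y = "Signal", colour = NULL)
}

#' @export
autoplot.pac_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$phase, y = .data$mean_amplitude)) +
    ggplot2::geom_col(width = 2 * pi / object$n_bins * 0.9) +
    ggplot2::labs(x = "Phase (rad)", y = "Mean amplitude",
                  title = sprintf("Modulation index = %.3g", object$mi))
}

#' Topographic statistic bar display
#'
#' The package computes topographic map values (rescaled significance per
#' electrode) but does not render scalp interpolations; this bar display
#' shows the same numbers per electrode.
#'
#' @param map a tibble from [topo_stat_map()].
#' @return A ggplot object.
#' @export
plot_topo_values <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(
    x = stats::reorder(.data$electrode, -.data$value),
    y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of most significant statistic")
}
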