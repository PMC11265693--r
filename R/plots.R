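#' Plot the fast variable of a trajectory
#'
#' One line per region; seizing regions show large-amplitude oscillations
#' of the fast variable.
#'
#' @param object A `vep_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vep_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, dplyr::starts_with("x_"),
    names_to = "region", names_prefix = "x_", values_to = "x"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$x,
                                     colour = .data$region)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = "time (model units)", y = "fast variable x")
}

#' Plot SEEG sensor series
#'
#' @param object A `sensor_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensor_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, dplyr::starts_with("s_"),
    names_to = "channel", names_prefix = "s_", values_to = "signal"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$signal,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = "time (model units)", y = "sensor signal")
}

#' Plot the best-so-far convergence trace of a fit
#'
#' @param object A `vep_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vep_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$evals, .data$cost)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "evaluations", y = "best RMSE")
}

#' Parallel-coordinates plot of uncertainty bands
#'
#' Shaded percentile bands per parameter around the median line, in
#' bounds-normalized units.
#'
#' @param object A `uq_bands` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uq_bands <- function(object, ...) {
  wide <- tidyr::pivot_wider(object, names_from = "percentile",
                             values_from = "value", names_prefix = "p")
  pcts <- sort(unique(object$percentile))
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$parameter))
  n_pairs <- length(pcts) %/% 2
  for (k in seq_len(n_pairs)) {
    lo <- paste0("p", pcts[k])
    hi <- paste0("p", pcts[length(pcts) + 1 - k])
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]),
      fill = "red", alpha = 0.25
    )
  }
  if (50 %in% pcts) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$p50), colour = "black")
  }
  p + ggplot2::labs(x = "parameter index", y = "normalized value") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
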