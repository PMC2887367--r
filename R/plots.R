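#' Plot an ideal errorless lap
#'
#' Speed and absolute-curvature profiles of the errorless lap on a common
#' time axis (curvature scaled down by 200, the conventional display), with
#' the figure-eight path as an inset-style second panel if `what = "path"`.
#'
#' @param object An `ideal_lap` tibble.
#' @param what `"profiles"` (speed and curvature vs time) or `"path"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ideal_lap
#' @export
autoplot.ideal_lap <- function(object, what = c("profiles", "path"), ...) {
  what <- match.arg(what)
  if (what == "path") {
    return(
      ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_path() +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "x (m)", y = "y (m)") +
        ggplot2::theme_minimal()
    )
  }
  d <- tidyr::pivot_longer(
    dplyr::transmute(object, t = .data$t, speed = .data$speed,
                     `|curvature| / 200` = abs(.data$curvature) / 200),
    -"t", names_to = "profile")
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$value,
                                  colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "m/s") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory log
#'
#' Hand and target paths, facetted by phase. Catch-trial windows are drawn
#' in a distinct colour on top of the hand path.
#'
#' @param object A `trajectory_log`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_log
#' @export
autoplot.trajectory_log <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_path(ggplot2::aes(.data$target_x, .data$target_y),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_path(ggplot2::aes(.data$hand_x, .data$hand_y),
                       colour = "steelblue", linewidth = 0.3) +
    ggplot2::facet_wrap(~ factor(phase, unique(d$phase))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
  if (any(d$catch == 1))
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(d, .data$catch == 1),
      ggplot2::aes(.data$hand_x, .data$hand_y),
      colour = "firebrick", size = 0.4)
  p
}

#' Plot per-lap indicators across the session
#'
#' One panel per indicator, laps on the x axis, phase boundaries marked.
#'
#' @param object A `lap_metrics` tibble from [lap_table()].
#' @param indicators Which indicator columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lap_metrics
#' @export
autoplot.lap_metrics <- function(object,
                                 indicators = c("delta", "delta_n", "NP",
                                                "CC", "DUR"),
                                 ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           dplyr::all_of(indicators),
                           names_to = "indicator")
  bounds <- object %>%
    group_by(.data$phase) %>%
    summarise(lap = min(.data$lap), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$lap, .data$value)) +
    ggplot2::geom_vline(data = bounds, ggplot2::aes(xintercept = .data$lap),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~ indicator, scales = "free_y") +
    ggplot2::labs(x = "lap", y = NULL) +
    ggplot2::theme_minimal()
}
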