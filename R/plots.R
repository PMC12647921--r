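# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a smoothed discharge-rate curve
#'
#' Smoothed curve with (optionally) the raw instantaneous rate points it was
#' fitted to, in the style of per-unit discharge panels.
#'
#' @param object A `smoothed_discharge`.
#' @param points Optional tibble with `time`/`rate` of instantaneous rates.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot smoothed_discharge
#' @export
autoplot.smoothed_discharge <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "Time (s)", y = "Discharge rate (pps)") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, alpha = 0.5, size = 0.8,
                                 colour = "grey30")
  }
  p
}

#' Plot an ascending discharge-versus-torque trajectory with its brace height
#'
#' Trajectory, the linear reference joining recruitment to peak discharge,
#' and the brace point.
#'
#' @param object An `ascending_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ascending_trajectory
#' @export
autoplot.ascending_trajectory <- function(object, ...) {
  ep <- attr(object, "endpoints")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$torque_pct, y = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "Torque (%MVT)", y = "Smoothed discharge rate (pps)") +
    ggplot2::theme_minimal()
  if (!is.null(ep)) {
    ref <- tibble::tibble(
      torque_pct = c(ep$recruit[["torque"]], ep$peak[["torque"]]),
      rate = c(ep$recruit[["rate"]], ep$peak[["rate"]])
    )
    p <- p + ggplot2::geom_line(data = ref, linetype = "dashed",
                                colour = "grey40")
  }
  p
}

#' Group-level delta-F summary plot
#'
#' Per-group, per-intensity distribution of unit delta-F values with group
#' means, faceted by recruitment-threshold bin.
#'
#' @param deltaf Delta-F table from [compute_deltaf()].
#' @return A ggplot.
#' @export
plot_deltaf_groups <- function(deltaf) {
  d <- deltaf |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::mutate(intensity = intensity_label(.data$intensity))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity,
                                  y = .data$delta_f_pps,
                                  colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~bin) +
    ggplot2::labs(x = "Contraction intensity",
                  y = expression(Delta * "F (pps)"), colour = "Group") +
    ggplot2::theme_minimal()
}
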