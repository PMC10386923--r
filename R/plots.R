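#' Plot response kernel families
#'
#' One curve per step moment, coloured by the time from the step to the
#' end of the movement, faceted by perturbation type. Compensatory
#' responses are positive for both types.
#'
#' @param kernels An `rc_kernels` tibble from [kernel_matrix()].
#' @return A ggplot object.
#' @export
plot_kernels <- function(kernels) {
  ggplot2::ggplot(
    kernels,
    ggplot2::aes(
      x = .data$lag_ms, y = .data$value,
      group = .data$k, colour = .data$step_time_before_end_ms
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_viridis_c(name = "step before end (ms)") +
    ggplot2::facet_wrap(~perturb_type) +
    ggplot2::labs(
      x = "time after step (ms)",
      y = expression("compensatory acceleration difference" ~ (mm / s^2))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cursor-vs-target lag-slice comparison
#'
#' Scatter of cursor against target response per step moment, one panel
#' per lag, with the fitted through-origin line. Points on a straight
#' line through the origin indicate that cursor and target response
#' vigour grow in the same way during the movement.
#'
#' @param vigour A `vigour_summary` from [vigour_summary()].
#' @return A ggplot object.
#' @export
plot_vigour_pairs <- function(vigour) {
  slopes <- vigour$fits[, c("lag_ms", "origin_slope")]
  ggplot2::ggplot(
    vigour$pairs,
    ggplot2::aes(x = .data$target, y = .data$cursor)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_abline(
      data = slopes,
      ggplot2::aes(slope = .data$origin_slope, intercept = 0),
      colour = "grey40", linetype = 2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$step_time_before_end_ms)
    ) +
    ggplot2::scale_colour_viridis_c(name = "step before end (ms)") +
    ggplot2::facet_wrap(~lag_ms, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = expression("response to target step" ~ (mm / s^2)),
      y = expression("response to cursor step" ~ (mm / s^2))
    ) +
    ggplot2::theme_minimal()
}
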