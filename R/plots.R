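# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the learning-walk trajectories of a series or cohort
#'
#' @param object an `lw_series` or `lw_cohort`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lw_series <- function(object, ...) {
  tr <- object$trajectories
  ggplot2::ggplot(tr, ggplot2::aes(.data$x, .data$y,
                                   colour = factor(.data$walk))) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::annotate("point", 0, 0, shape = 8, size = 3, colour = "orange") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "walk", x = "x (m)", y = "y (m)",
                  title = "Learning walks") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lw_series
#' @export
autoplot.lw_cohort <- function(object, ...) {
  autoplot.lw_series(list(trajectories = object$trajectories)) +
    ggplot2::facet_wrap(~agent)
}

#' Plot cue-weight dynamics
#'
#' Median and interquartile band of the normalised cue-weight shares over
#' normalised step index, per walk.
#'
#' @param trajectories cohort trajectory tibble.
#' @param n_bins normalised step bins.
#' @return a ggplot.
#' @export
plot_weight_dynamics <- function(trajectories, n_bins = 100) {
  pr <- weight_dynamics(trajectories, n_bins)$profiles
  ggplot2::ggplot(pr, ggplot2::aes(.data$bin, .data$q50, colour = .data$cue,
                                   fill = .data$cue)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~walk, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "normalised step", y = "weight share") +
    ggplot2::theme_minimal()
}

#' Plot homing-test outcomes on the release grid
#'
#' @param outcomes a [homing_test()] or [homing_by_experience()] tibble.
#' @return a ggplot.
#' @export
plot_homing_grid <- function(outcomes) {
  p <- ggplot2::ggplot(outcomes,
                       ggplot2::aes(factor(.data$angle_deg),
                                    factor(.data$dist_m),
                                    fill = .data$success)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black")) +
    ggplot2::labs(x = "release bearing (deg)", y = "release distance (m)") +
    ggplot2::theme_minimal()
  if ("walks" %in% names(outcomes)) {
    if ("agent" %in% names(outcomes) && length(unique(outcomes$agent)) > 1)
      p <- p + ggplot2::facet_grid(agent ~ walks)
    else p <- p + ggplot2::facet_wrap(~walks)
  }
  p
}
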