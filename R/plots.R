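#' Plot operating characteristics across a scenario grid
#'
#' Draws one of the standard comparison curves from a [run_grid()]
#' metrics table: rejection rate (power / type I error), percentage of
#' patients on the superior arm, average bias, or MSE of the
#' treatment-effect estimator, against `theta_b`, one line per design.
#'
#' @param metrics A metrics tibble from [run_grid()] (or rows built with
#'   [summarize_trials()] plus `design`/`theta_b` columns).
#' @param measure One of `"reject_rate"`, `"pct_superior"`, `"bias"`,
#'   `"mse"`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics,
                         measure = c("reject_rate", "pct_superior",
                                     "bias", "mse")) {
  measure <- match.arg(measure)
  lab <- c(
    reject_rate = "Rejection rate (power / type I error)",
    pct_superior = "% patients on superior arm",
    bias = "Average bias of treatment-effect estimate",
    mse = "MSE of treatment-effect estimate"
  )[[measure]]
  ggplot2::ggplot(metrics, ggplot2::aes(
    x = .data$theta_b, y = .data[[measure]],
    colour = .data$design, group = .data$design
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(theta[B]), y = lab, colour = "design") +
    ggplot2::theme_minimal()
}

#' Plot the allocation trajectory of a batch
#'
#' The per-patient fraction of replicates allocated to the superior arm
#' ([allocation_trajectory()]). For a constrained design this shows the
#' probability climbing towards the degree of randomisation and then
#' oscillating over the final patients while the minimum per-arm sample
#' size is being enforced.
#'
#' @param object A `trial_batch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_batch
#' @export
autoplot.trial_batch <- function(object, ...) {
  traj <- allocation_trajectory(object)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$patient, y = .data$prop_superior)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "patient", y = "P(allocated to superior arm)",
      title = sprintf("%s design, n = %d, theta_a = %g, theta_b = %g",
                      object$design, object$n, object$theta_a, object$theta_b)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
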