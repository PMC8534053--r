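#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trial
#'
#' Spaghetti plot of tumor volume over time, one panel per treatment arm, on
#' a log scale with the LOQ as a dashed reference line.
#'
#' @param object A `sim_trial` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_trial
#' @export
autoplot.sim_trial <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$time, y = .data$dv,
                               group = .data$animal_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$design$loq, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Time (days)", y = expression(Tumor~volume~(mm^3)))
}

#' Plot state trajectories of one simulated animal
#'
#' @param trajectory A [simulate_profile()] tibble.
#' @param states Which state variables to show.
#' @return A ggplot, one facet per state (free y scales).
#' @export
plot_profile <- function(trajectory,
                         states = c("apc", "cd8_act", "ts")) {
  long <- tidyr::pivot_longer(trajectory[, c("time", states)], -"time",
                              names_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "Time (days)", y = NULL)
}

#' Plot a numerical predictive check
#'
#' Per-arm 5-95% simulated bands (with the median) for the cure and
#' partial-response probabilities, with observed values overlaid when
#' present.
#'
#' @param object An `npc_summary` tibble from [npc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot npc_summary
#' @export
autoplot.npc_summary <- function(object, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$arm)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                            linewidth = 4, colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(y = .data$p50), shape = 3, size = 3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "Probability") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (any(is.finite(object$observed))) {
    g <- g + ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                                 colour = "blue", size = 2)
  }
  g
}

#' Plot a grid-exploration result
#'
#' Scatter of responder percentage against an exposure metric, one panel per
#' arm.
#'
#' @param records A [grid_exploration()] tibble.
#' @param metric `"auc_cd8"` or `"auc_resistance_inhibition"`.
#' @return A ggplot.
#' @export
plot_exploration <- function(records, metric = "auc_cd8") {
  long <- tidyr::pivot_longer(
    records, c("pct_responder", "pct_partial", "pct_non"),
    names_to = "status", values_to = "pct"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[metric]], y = .data$pct,
                                     colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = metric, y = "% of simulated animals")
}
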