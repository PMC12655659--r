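#' Plot a concentration-time profile
#'
#' @param object A `radpk_profile` from [simulate_profile()] or
#'   [steady_state_window()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radpk_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)") +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo exposure distributions
#'
#' @param object A `radpk_mc` from [monte_carlo_exposures()].
#' @param ... Unused.
#' @return A ggplot of the per-subject metric distributions.
#' @export
autoplot.radpk_mc <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("auc_0_24", "cmax", "ctrough"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, fill = "#a6bddb") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free") +
    ggplot2::labs(title = object$label, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a visual predictive check
#'
#' Observed concentrations and percentile lines over the simulated median and
#' confidence ribbons, faceted by occasion.
#'
#' @param object A `radpk_vpc` from [vpc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radpk_vpc <- function(object, ...) {
  b <- object$bands
  ggplot2::ggplot(b, ggplot2::aes(x = .data$TIME)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p05_lo,
                                      ymax = .data$sim_p05_hi),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p95_lo,
                                      ymax = .data$sim_p95_hi),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p50_med)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p05_med), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p95_med), linetype = 2) +
    ggplot2::geom_point(data = object$observed,
                        ggplot2::aes(x = .data$TIME, y = .data$DV),
                        alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$OCC), scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)") +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit panels for a fitted model
#'
#' Observed versus population and individual predictions, and conditional
#' weighted residuals versus time and versus population prediction.
#'
#' @param data The fitted [event_table()].
#' @param fit A `radpk_fit`.
#' @return A list of four ggplots: `obs_vs_pred`, `obs_vs_ipred`,
#'   `cwres_vs_time`, `cwres_vs_pred`.
#' @export
plot_gof <- function(data, fit) {
  g <- gof_table(data, fit)
  base <- ggplot2::theme_minimal()
  list(
    obs_vs_pred = ggplot2::ggplot(g, ggplot2::aes(.data$PRED, .data$DV)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "Population prediction (ng/mL)", y = "Observed (ng/mL)") +
      base,
    obs_vs_ipred = ggplot2::ggplot(g, ggplot2::aes(.data$IPRED, .data$DV)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "Individual prediction (ng/mL)", y = "Observed (ng/mL)") +
      base,
    cwres_vs_time = ggplot2::ggplot(g, ggplot2::aes(.data$TIME, .data$CWRES)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "Time (h)", y = "CWRES") + base,
    cwres_vs_pred = ggplot2::ggplot(g, ggplot2::aes(.data$PRED, .data$CWRES)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "Population prediction (ng/mL)", y = "CWRES") + base
  )
}
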