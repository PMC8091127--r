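#' Goodness-of-fit panels
#'
#' Four standard diagnostic panels from a [residual_table()]: observations
#' versus population and individual predictions, |IWRES| versus IPRED, and
#' CWRES versus time.
#'
#' @param rt a [residual_table()].
#' @return list of ggplot objects named `obs_pred`, `obs_ipred`,
#'   `iwres_ipred`, `cwres_time`.
#' @export
plot_gof <- function(rt) {
  stopifnot(inherits(rt, "residual_table"))
  th <- ggplot2::theme_bw()
  list(
    obs_pred = ggplot2::ggplot(rt, ggplot2::aes(.data$PRED, .data$DV)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0) +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                           colour = "red") +
      ggplot2::labs(x = "Population prediction", y = "Observed SOFA") + th,
    obs_ipred = ggplot2::ggplot(rt, ggplot2::aes(.data$IPRED, .data$DV)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0) +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                           colour = "red") +
      ggplot2::labs(x = "Individual prediction", y = "Observed SOFA") + th,
    iwres_ipred = ggplot2::ggplot(rt, ggplot2::aes(.data$IPRED,
                                                   abs(.data$IWRES))) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                           colour = "red") +
      ggplot2::labs(x = "Individual prediction", y = "|IWRES|") + th,
    cwres_time = ggplot2::ggplot(rt, ggplot2::aes(.data$DAY, .data$CWRES)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::geom_hline(yintercept = c(-2, 2), linetype = 2) +
      ggplot2::labs(x = "Time (days)", y = "CWRES") + th)
}

#' Plot a prediction-corrected visual predictive check
#'
#' @param vpc a [pcvpc()] summary.
#' @return a ggplot object, facetted by stratum.
#' @export
plot_vpc <- function(vpc) {
  stopifnot(inherits(vpc, "vpc_summary"))
  ggplot2::ggplot(vpc, ggplot2::aes(.data$DAY, group = .data$PCTL)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$SIM_LO,
                                      ymax = .data$SIM_HI),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$SIM_MED), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$OBS), colour = "red") +
    ggplot2::facet_wrap(~STRATUM) +
    ggplot2::labs(x = "Time (days)",
                  y = "Prediction-corrected SOFA",
                  title = sprintf("pcVPC (%d simulations, %g%% CI)",
                                  attr(vpc, "n_sim"), attr(vpc, "ci"))) +
    ggplot2::theme_bw()
}

#' Plot day-7 SOFA versus exposure profiles
#'
#' @param profiles list of `day7_profile` frames from
#'   [simulate_day7_vs_auc()].
#' @return a ggplot object, facetted by baseline.
#' @export
plot_day7 <- function(profiles) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    p$BASELINE <- attr(p, "baseline")
    as.data.frame(p)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$AUC, .data$P50)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$P30, ymax = .data$P70),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::facet_wrap(~BASELINE, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Steady-state AUC (h*ng/mL)", y = "Day-7 SOFA") +
    ggplot2::theme_bw()
}
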