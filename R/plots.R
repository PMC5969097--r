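method_labels <- c(
  mv_linear_basic = "Linear regression (basic adjustment)",
  mv_linear_full = "Linear regression (full adjustment)",
  iv_2sls = "Instrumental variable (2SLS)",
  ps_matched = "Propensity matched"
)

#' Horizon-curve figure for one outcome
#'
#' Risk differences per 100 patients treated against follow-up horizon, one
#' curve per estimation method with 95% confidence ribbons — the canonical
#' way to contrast conditional-exchangeability estimators with the
#' instrumental-variable curve over follow-up.
#'
#' @param estimates estimate rows from [run_pipeline()] or the individual
#'   estimators.
#' @param outcome outcome label to plot.
#' @param methods methods to include (default: linear basic/full and IV).
#' @return a ggplot object.
#' @export
horizon_curve_plot <- function(estimates, outcome,
                               methods = c("mv_linear_basic",
                                           "mv_linear_full", "iv_2sls")) {
  d <- estimates[estimates$outcome == outcome &
                   estimates$method %in% methods &
                   !is.na(estimates$horizon) &
                   estimates$scale == "risk difference per 100", ]
  if (!nrow(d)) abort_prefiv("no risk-difference estimates for ", outcome)
  d$method <- factor(d$method, levels = methods,
                     labels = method_labels[methods])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$horizon, y = .data$estimate,
                                  colour = .data$method, fill = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_x_continuous(breaks = sort(unique(d$horizon))) +
    ggplot2::labs(x = "Months since first prescription",
                  y = "Risk difference per 100 patients treated",
                  colour = NULL, fill = NULL,
                  title = sprintf("Effect of varenicline vs NRT on %s", outcome)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Forest figure at a single horizon
#'
#' Point estimates and 95% confidence intervals for every outcome and
#' method at one follow-up horizon.
#'
#' @param estimates estimate rows.
#' @param horizon horizon in months.
#' @param scale which estimate scale to show (default risk differences).
#' @return a ggplot object.
#' @export
forest_plot <- function(estimates, horizon,
                        scale = "risk difference per 100") {
  d <- estimates[!is.na(estimates$horizon) & estimates$horizon == horizon &
                   estimates$scale == scale, ]
  if (!nrow(d)) abort_prefiv("no estimates on scale '", scale,
                             "' at horizon ", horizon)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$outcome,
                                  colour = .data$method)) +
    ggplot2::geom_vline(xintercept = if (scale == "odds ratio") 1 else 0,
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = scale, y = NULL, colour = NULL,
                  title = sprintf("Estimates at %d months", horizon)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
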