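#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars from the ICER at each parameter's low value to the ICER
#' at its high value, widest spread on top, with a vertical line at the
#' base-case ICER.
#'
#' @param tornado Result of [one_way_dsa()].
#' @param base_icer Base-case ICER for the reference line (optional).
#' @param top Number of parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, base_icer = NULL, top = 15) {
  stopifnot(is.data.frame(tornado),
            all(c("name", "icer_at_low", "icer_at_high", "spread") %in%
                  names(tornado)))
  df <- utils::head(dplyr::arrange(tornado, dplyr::desc(.data$spread)), top)
  df$name <- factor(df$name, levels = rev(df$name))
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_at_low, xend = .data$icer_at_high,
                   yend = .data$name),
      linewidth = 4, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity analysis")
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer,
                                 linetype = "dashed")
  }
  p
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df Result of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  stopifnot(all(c("wtp", "strategy", "probability") %in% names(ceac_df)))
  ggplot2::ggplot(ceac_df,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective", colour = NULL,
                  title = "Cost-effectiveness acceptability curve")
}

#' Cost-effectiveness plane of PSA draws
#'
#' Scatter of incremental QALYs against incremental cost across draws,
#' with the willingness-to-pay threshold as a dashed line through the
#' origin.
#'
#' @param object A `cea_psa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly,
                               y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = sprintf("Cost-effectiveness plane (%s vs %s)",
                                  object$comparator, object$reference))
}

#' Cohort trace plot
#'
#' State occupancy over the model horizon for one arm.
#'
#' @param trace A trace from [run_cohort()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, title = "Cohort trace") {
  long <- tidyr::pivot_longer(trace[c("cycle", "pfs", "pd", "death")],
                              -"cycle", names_to = "state",
                              values_to = "occupancy")
  long$state <- factor(long$state, levels = c("pfs", "pd", "death"),
                       labels = c("Progression-free", "Progressed", "Dead"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Model cycle (6 weeks)", y = "State occupancy",
                  colour = NULL, title = title)
}
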