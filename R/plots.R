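#' Cost-effectiveness plane
#'
#' Scatter of incremental QALYs against incremental costs across PSA draws,
#' with quadrant axes and an optional willingness-to-pay line. Draws below
#' the WTP line are cost-effective at that threshold.
#'
#' @param object A `cea_psa` tibble from [run_psa()].
#' @param wtp Willingness-to-pay slope to overlay, $/QALY; `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, wtp = 50000, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$inc_qaly, y = .data$inc_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost ($)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa A `cea_psa` tibble, or a precomputed curve from [ceac()].
#' @param wtp WTP grid when `psa` is a sample (default $0-$200,000).
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, wtp = seq(0, 200000, by = 1000)) {
  curve <- if (all(c("wtp", "prob_cost_effective") %in% names(psa))) psa else ceac(psa, wtp)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay ($/QALY)", y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity analyses
#'
#' Horizontal bars spanning each parameter's ICER range, widest spread on
#' top, with a reference line at the base-case ICER when available.
#'
#' @param object A `cea_tornado` tibble from [tornado_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, ...) {
  df <- dplyr::mutate(object,
    parameter = factor(.data$parameter, levels = rev(.data$parameter))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_min, xend = .data$icer_max, yend = .data$parameter),
      linewidth = 4, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::labs(
      x = "ICER ($/QALY)", y = NULL,
      title = "One-way sensitivity analyses"
    ) +
    ggplot2::theme_minimal()
  base_icer <- attr(object, "base_icer")
  if (!is.null(base_icer) && is.finite(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed")
  }
  p
}
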