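#' Heatmap of a correlation matrix
#'
#' Lower-triangle tile plot with the correlation printed in each cell,
#' mirroring the layout of the study's correlation tables.
#'
#' @param object A [corr_matrix].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corr_matrix
#' @export
autoplot.corr_matrix <- function(object, ...) {
  td <- tidy(object)
  td$var1 <- factor(td$var1, levels = object$labels)
  td$var2 <- factor(td$var2, levels = object$labels)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$var2, y = .data$var1,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", round_half_up(.data$r, 2))), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::scale_y_discrete(limits = rev(levels(td$var1))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Model summary figure: R-squared and partial correlations
#'
#' One panel per sex: the total model R-squared of each compartment
#' (columns) and point-ranges of the per-predictor partial correlations
#' with their confidence intervals -- the layout used to compare how well
#' anthropometry predicts each compartment.
#'
#' @param object A `cohort_analysis` from [analyze_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_analysis
#' @export
autoplot.cohort_analysis <- function(object, ...) {
  m <- object$models
  m$outcome <- factor(m$outcome, levels = unique(m$outcome))
  r2 <- dplyr::distinct(m, .data$sex, .data$outcome, .data$r_squared)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$outcome)) +
    ggplot2::geom_col(data = r2,
                      ggplot2::aes(y = .data$r_squared),
                      fill = "grey85", width = 0.65) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$partial_r, ymin = .data$ci_low,
                   ymax = .data$ci_high, colour = .data$term),
      position = ggplot2::position_dodge(width = 0.5), size = 0.3) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = NULL,
                  y = "model R² (bars) / partial r (points, 95% CI)",
                  colour = "predictor") +
    ggplot2::theme_minimal()
}
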