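#' QQ plot of simulated p-values against Uniform(0, 1)
#'
#' One point per replicate and method, on the scale of the familiar
#' uniform quantile-quantile display: well-calibrated p-values track the
#' diagonal, anti-conservative ones fall below it.
#'
#' @param object A [simulate_type1()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kmeans_sim_type1
#' @export
autoplot.kmeans_sim_type1 <- function(object, ...) {
  df <- dplyr::mutate(
    dplyr::arrange(dplyr::group_by(object$results, .data$method), .data$p),
    expected = (seq_along(.data$p) - 0.5) / length(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$p,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = "Uniform(0, 1) quantiles", y = "observed p-value",
                  colour = NULL,
                  title = "Calibration under the global null") +
    ggplot2::theme_minimal()
}

#' Detection probability and conditional power curves
#'
#' @param object A [simulate_power()] result.
#' @param ... Unused.
#' @return A ggplot object faceted into the detection-probability curve
#'   (method-independent) and the conditional-power curves per method.
#' @method autoplot kmeans_sim_power
#' @export
autoplot.kmeans_sim_power <- function(object, ...) {
  s <- object$summary
  det <- dplyr::distinct(s, .data$delta, .data$detection_prob)
  det <- dplyr::mutate(det, panel = "detection probability",
                       value = .data$detection_prob, method = "k-means")
  pow <- dplyr::mutate(s, panel = "conditional power",
                       value = .data$conditional_power)
  df <- dplyr::bind_rows(det[, c("delta", "method", "panel", "value")],
                         pow[, c("delta", "method", "panel", "value")])
  ggplot2::ggplot(df, ggplot2::aes(.data$delta, .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = expression(delta), y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
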