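# ggplot2 autoplot methods for the result objects.

#' @describeIn repeatability_report Bland-Altman plot with dashed 95% limits
#'   of agreement.
#' @param object A `repeatability_report`.
#' @export
autoplot.repeatability_report <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean_score, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Mean predicted score", y = "Test-retest difference",
                  title = sprintf("Disagreement %.2f | normalized 95%% LoA %.2f",
                                  object$disagreement_rate, object$loa95)) +
    ggplot2::theme_minimal()
}

#' @describeIn calibration_curve Reliability diagram with identity line and
#'   per-bin 95% predicted-value spans.
#' @param object A `calibration_report`.
#' @export
autoplot.calibration_report <- function(object, ...) {
  bins <- dplyr::filter(object$bins, .data$count > 0L)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_pred,
                                     y = .data$observed_freq)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$pred_lo,
                                         xmax = .data$pred_hi), height = 0.02) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability", y = "Observed frequency",
                  title = sprintf("Brier score %.3f", object$brier)) +
    ggplot2::theme_minimal()
}

#' @describeIn sweep_iterations Repeatability against the number of MC
#'   iterations, with the dropout-disabled single pass as a starred baseline.
#' @param object An `mc_sweep`.
#' @param ... Unused.
#' @export
autoplot.mc_sweep <- function(object, ...) {
  df <- as_tibble(object)
  base <- tibble(n = 1, loa95 = attr(object, "baseline_loa95"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$loa95)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = base, colour = "darkorange", shape = 8, size = 3) +
    ggplot2::labs(x = "MC iterations", y = "Normalized 95% LoA",
                  title = "Repeatability vs MC iterations (star: dropout disabled)") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_model Bland-Altman plot of the evaluation.
#' @param object A `model_evaluation`.
#' @param ... Unused.
#' @export
autoplot.model_evaluation <- function(object, ...) {
  autoplot(object$repeatability, ...)
}
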