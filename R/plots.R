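# ggplot2 views of traces, error curves and sweep grids.

#' Plot a CGM day-curve with threshold lines
#'
#' @param trace A [glucose_trace()].
#' @param thresholds Optional [threshold_config()] drawn as dashed lines.
#' @return A ggplot object: glucose (mmol/L) against time, faceted by day.
#' @export
plot_trace <- function(trace, thresholds = NULL) {
  stopifnot(inherits(trace, "glucose_trace"))
  df <- tibble::tibble(
    day = rep(seq_len(trace$n_days), each = trace$day_length),
    hour = rep(slot_midpoints() / 60, trace$n_days),
    glucose = trace$values
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$glucose)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "hour of day", y = "glucose (mmol/L)",
      title = sprintf("patient %s", trace$patient_id)
    )
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(thresholds$lower, thresholds$upper),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.glucose_trace <- function(object, ...) plot_trace(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.holdout_eval <- function(object, ...) {
  ggplot2::ggplot(object$staged, ggplot2::aes(x = .data$round, y = .data$error_rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iterations", y = "test error rate",
                  title = sprintf("%s AdaBoost hold-out error", object$metrics$variant))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_eval <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$round, y = .data$error_rate,
                               group = .data$fold)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_line(data = object$mean_curve,
                       ggplot2::aes(group = NULL), linewidth = 0.8) +
    ggplot2::labs(x = "iterations", y = "test error rate",
                  title = sprintf("%d-fold CV, %s AdaBoost", object$k, object$variant))
}

#' Error-vs-iteration curves of a threshold sweep
#'
#' One panel per upper threshold, one line per boosting variant.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$round, y = .data$error_rate,
                               colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mu, labeller = ggplot2::labeller(
      mu = function(v) paste0("μ = ", v, " mmol/L"))) +
    ggplot2::labs(x = "iterations", y = "test error rate", colour = "variant")
}
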