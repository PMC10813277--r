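#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot single-factor sweeps and the influence ranking
#'
#' Faceted stress-vs-level curves for the six single-factor sweeps, with
#' excluded (no-clear-trend) variables drawn dashed.
#'
#' @param object An `implant_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.implant_sensitivity <- function(object, ...) {
  long <- tidy(object)
  long$trend <- ifelse(long$monotone_flag == "none", "no clear trend",
                       "monotone")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$stress_MPa,
                                     linetype = .data$trend)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::scale_linetype_manual(
      values = c("monotone" = "solid", "no clear trend" = "dashed")) +
    ggplot2::labs(x = "level", y = "cortical von Mises stress (MPa)",
                  linetype = NULL,
                  title = "Single-factor stress sweeps at the baseline placement")
}

#' @rdname autoplot.implant_sensitivity
#' @param x An `implant_sensitivity`.
#' @export
plot_influence <- function(x, ...) {
  r <- x$ranking
  r$variable <- factor(r$variable, levels = rev(r$variable))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$relative_range_pct,
                                  y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative stress range (%)", y = NULL,
                  title = "Design-variable influence on cortical stress")
}

#' Observed-vs-predicted plot for a fitted surrogate
#'
#' @param object An `implant_rom`.
#' @param data The response tibble to predict on (e.g. the training data).
#' @param ... Unused.
#' @return A ggplot with the identity line.
#' @export
autoplot.implant_rom <- function(object, data, ...) {
  df <- tibble::tibble(observed = data[[object$response]],
                       predicted = as.numeric(predict(object, data)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("observed", object$response),
                  y = paste("predicted", object$response),
                  title = "Surrogate fit: observed vs predicted")
}

#' Stress map of assessed placements
#'
#' Stress per candidate, colored by the green/red safety status with the
#' threshold drawn as a horizontal line.
#'
#' @param object An `implant_assessment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.implant_assessment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$candidate <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate,
                                   y = .data$cortical_stress_MPa,
                                   colour = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = df$threshold_MPa[1], linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(green = "#2e7d32", red = "#c62828"),
                                 na.value = "grey50") +
    ggplot2::labs(x = "candidate", y = "cortical von Mises stress (MPa)",
                  title = "Placement safety assessment")
}

#' @importFrom rlang .data
NULL
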