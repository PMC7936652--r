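#' Annotated per-transcript plot
#'
#' Observed counts per sample for one checked transcript, coloured by the
#' factor of interest, with point size proportional to the inferred
#' sequencing-depth factor (posterior mean exposure), dashed error bars for
#' the discovery-stage 95% theoretical interval, solid bars for the
#' test-stage interval at the user coverage, and flagged observations in
#' red.
#'
#' @param report an [OutlierReport-class].
#' @param transcript transcript id to plot.
#' @return a ggplot object.
#' @export
plotTranscript <- function(report, transcript) {
  calls <- report@calls
  d <- calls[calls$transcript == transcript, , drop = FALSE]
  if (!nrow(d)) stop("transcript not in the report: ", transcript)
  fit <- report@discovery
  mod <- fit@model
  expo <- exp(colMeans(fit@exposure))[match(d$sample, mod@samples)]
  ds <- mod@design
  ci <- mod@coefIndex
  d$factor_level <- factor(ds[match(d$sample, mod@samples), ci])
  d$exposure <- expo
  d$flagged <- d$final_flag
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sample)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$discovery_lower,
                   ymax = .data$discovery_upper),
      linetype = "dashed", width = 0.3, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     size = .data$exposure,
                                     colour = .data$factor_level)) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(title = transcript, y = "read count", x = NULL,
                  size = "depth factor", colour = "factor of interest") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (any(!is.na(d$test_lower))) {
    dt <- d[!is.na(d$test_lower), , drop = FALSE]
    p <- p + ggplot2::geom_errorbar(
      data = dt,
      ggplot2::aes(ymin = .data$test_lower, ymax = .data$test_upper),
      width = 0.3, colour = ifelse(dt$flagged, "red", "black"))
  }
  p
}

#' Calibration scatter plot
#'
#' Empirical transcript-level FPR against the nominal user FPR for the
#' clean-data runs, with the identity line and the fitted regression.
#'
#' @param calib a `ppc_calibration` result.
#' @return a ggplot object.
#' @export
plotCalibration <- function(calib) {
  d <- calib$runs
  d <- d[d$dataset == "clean" & d$mode == "two_step", , drop = FALSE]
  if (!nrow(d)) stop("no clean-data runs in this calibration result")
  lab <- if (!is.null(calib$fprSummary)) {
    sprintf("slope = %.2f, R² = %.2f", calib$fprSummary$slope,
            calib$fprSummary$r2)
  } else ""
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nominal,
                                  y = .data$empirical_fpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "nominal false positive rate",
                  y = "empirical transcript-level FPR", subtitle = lab) +
    ggplot2::theme_bw()
}

#' ROC comparison of the one- and two-step modes
#'
#' @param calib a `ppc_calibration` result run with injected outliers.
#' @return a ggplot object.
#' @export
plotRoc <- function(calib) {
  if (is.null(calib$roc)) stop("no injected-data runs in this result")
  ggplot2::ggplot(calib$roc,
                  ggplot2::aes(x = .data$empirical_fpr,
                               y = .data$tpr_transcript,
                               colour = .data$mode)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_bw()
}
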