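#' Plot an interferogram
#'
#' @param object An `ftims_interferogram`.
#' @param ... Unused.
#' @return A ggplot: averaged detector signal against gate frequency.
#' @export
autoplot.ftims_interferogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frequency_hz, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "gate frequency (Hz)", y = "averaged signal (a.u.)",
                  title = "Stepped-frequency interferogram") +
    ggplot2::theme_minimal()
}

#' Plot a mobility spectrum, optionally with fitted peaks
#'
#' @param object An `ftims_spectrum`.
#' @param peaks Optional peak table from [fit_peaks()] /
#'   [analyze_spectrum()]; fitted centres are marked.
#' @param ... Unused.
#' @return A ggplot of intensity against drift time.
#' @export
autoplot.ftims_spectrum <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$drift_time_ms,
                                    y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "drift time (ms)", y = "intensity (a.u.)",
                  title = "Reconstructed mobility spectrum") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$td),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a frequency-parameter study
#'
#' Resolving power (points, with +/- 1 sd error bars over replicates) and
#' predicted acquisition time (dashed line, secondary axis) against the
#' studied plan parameter.
#'
#' @param object An `ftims_study` from [run_frequency_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ftims_study <- function(object, ...) {
  variable <- attr(object, "variable") %||% "value"
  scale <- max(object$mean_rp, na.rm = TRUE) /
    max(object$duration_s, na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_rp)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rp - .data$sd_rp,
                                        ymax = .data$mean_rp + .data$sd_rp),
                           width = 0) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$duration_s * scale),
                       linetype = "dashed") +
    ggplot2::scale_y_continuous(
      "resolving power",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "acquisition time (s)")) +
    ggplot2::labs(x = paste0(variable, " (Hz)"),
                  title = "Frequency-parameter optimisation") +
    ggplot2::theme_minimal()
}

#' Side-by-side single-gate vs FT metric plot
#'
#' @param report An `ftims_comparison` from [build_report()].
#' @param metric `"rp"` (resolving power) or `"snr"`.
#' @return A ggplot dot plot, one row per compound, both modes.
#' @export
plot_comparison <- function(report, metric = c("rp", "snr")) {
  metric <- match.arg(metric)
  rows <- tidy(report)
  cols <- paste0(metric, c("_sg", "_ft"))
  long <- tidyr::pivot_longer(rows[, c("compound", cols)],
                              dplyr::all_of(cols),
                              names_to = "mode", values_to = "value")
  long$mode <- ifelse(grepl("_ft$", long$mode), "stepped FT", "single gate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$compound,
                                     colour = .data$mode)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (metric == "rp") "resolving power" else "S/N",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
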