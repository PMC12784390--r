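#' Tidy a comparison report
#'
#' @param x An `ftims_comparison`.
#' @param ... Unused.
#' @return The per-compound rows as a tibble.
#' @export
tidy.ftims_comparison <- function(x, ...) {
  x$rows
}

#' One-row summary of a comparison report
#'
#' @param x An `ftims_comparison`.
#' @param ... Unused.
#' @return One-row tibble with mode means and percent increases.
#' @export
glance.ftims_comparison <- function(x, ...) {
  x$summary
}

#' Tidy a mobility spectrum into its fitted peaks
#'
#' @param x An `ftims_spectrum`.
#' @param cell Drift cell for the mobility column.
#' @param min_prominence Passed to [fit_peaks()].
#' @param ... Unused.
#' @return The [analyze_spectrum()] peak table.
#' @export
tidy.ftims_spectrum <- function(x, cell = drift_cell(),
                                min_prominence = 0.1, ...) {
  analyze_spectrum(x, cell, min_prominence)
}

#' One-row summary of a mobility spectrum
#'
#' @param x An `ftims_spectrum`.
#' @param ... Unused.
#' @return One-row tibble: axis extent, bin widths, band and window used.
#' @export
glance.ftims_spectrum <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    td_max_ms = max(x$drift_time_ms),
    bin_ms = attr(x, "bin_ms") %||% NA_real_,
    resolution_bin_ms = attr(x, "resolution_bin_ms") %||% NA_real_,
    f_min = attr(x, "f_min") %||% NA_real_,
    f_max = attr(x, "f_max") %||% NA_real_,
    f_step = attr(x, "f_step") %||% NA_real_,
    window = attr(x, "window") %||% NA_character_,
    zero_pad_factor = attr(x, "zero_pad_factor") %||% NA_integer_
  )
}
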