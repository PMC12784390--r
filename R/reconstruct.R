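#' Deconvolute an interferogram into a drift-time mobility spectrum
#'
#' The per-frequency dual-gate signal is periodic in frequency with period
#' `1/td` for each drift time `td` present, so a magnitude FFT over the
#' uniform frequency grid maps ions onto a drift-time axis. The pipeline
#' is: subtract the signal mean (the correlation signal carries a large DC
#' pedestal, about `duty/2` per unit abundance, that would otherwise leak
#' over low drift times), apodise, zero-pad, FFT, and report the magnitude
#' spectrum (phase is arbitrary under asynchronous triggering). The
#' conjugate axis has bin width `1 / (N_fft * f_step)` and extends to the
#' maximum representable drift time `1 / (2 * f_step)`. Frequencies below
#' the grid start are treated as absent -- no extrapolation towards 0 Hz --
#' which for a magnitude spectrum only shifts phase.
#'
#' @param ig An `ftims_interferogram` (uniform, strictly increasing
#'   frequency grid).
#' @param window Apodisation: `"rectangular"` (default; no shaping) or
#'   `"hann"`.
#' @param zero_pad_factor Integer >= 1; the FFT length is at least this
#'   multiple of the data length (default 8, so peak-width estimates are
#'   not bin-limited).
#' @return A mobility spectrum: tibble with columns `drift_time_ms`,
#'   `intensity` (>= 0), class `ftims_spectrum`. Attributes record
#'   `f_step`, `f_min`, `f_max`, `window`, `zero_pad_factor`, the padded
#'   axis spacing `bin_ms` and the transform-limited resolution bin
#'   `resolution_bin_ms = 1000 / (N_data * f_step)`.
#' @examples
#' ig <- simulate_interferogram(plan_stepped(10, 5, 4000, 4),
#'                              fixture_mixture("rip")$ions)
#' sp <- reconstruct_spectrum(ig)
#' sp$drift_time_ms[which.max(sp$intensity)]   # ~20 ms
#' @export
reconstruct_spectrum <- function(ig, window = c("rectangular", "hann"),
                                 zero_pad_factor = 8) {
  window <- match.arg(window)
  if (!all(c("frequency_hz", "signal") %in% names(ig))) {
    abort("`ig` must have columns frequency_hz and signal",
          class = "ftims_error_interferogram")
  }
  f <- ig$frequency_hz
  n <- length(f)
  if (n < 8) abort("interferogram too short to transform",
                   class = "ftims_error_interferogram")
  df <- diff(f)
  f_step <- stats::median(df)
  if (any(df <= 0) || any(abs(df - f_step) > 1e-9 * f_step)) {
    abort(paste("frequency grid is not uniform and increasing;",
                "resample onto a uniform grid before reconstructing"),
          class = "ftims_error_interferogram")
  }
  zero_pad_factor <- max(1L, as.integer(zero_pad_factor))
  x <- ig$signal - mean(ig$signal)
  w <- switch(window,
    rectangular = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  )
  n_fft <- nextn(zero_pad_factor * n, c(2, 3, 5))
  X <- fft(c(x * w, rep(0, n_fft - n)))
  n_keep <- floor(n_fft / 2) + 1
  idx <- seq_len(n_keep)
  td_ms <- 1000 * (idx - 1) / (n_fft * f_step)
  intensity <- 2 * Mod(X[idx]) / sum(w)
  out <- tibble(drift_time_ms = td_ms, intensity = intensity)
  class(out) <- c("ftims_spectrum", class(out))
  attr(out, "f_step") <- f_step
  attr(out, "f_min") <- f[1]
  attr(out, "f_max") <- f[n]
  attr(out, "window") <- window
  attr(out, "zero_pad_factor") <- zero_pad_factor
  attr(out, "n_data") <- n
  attr(out, "bin_ms") <- 1000 / (n_fft * f_step)
  attr(out, "resolution_bin_ms") <- 1000 / (n * f_step)
  out
}

# half-amplitude main-lobe widths of window transforms, in units of
# 1/bandwidth (verified numerically in the test suite by zero-padded FFT
# of the windows themselves)
window_fwhm_constant <- c(rectangular = 1.2067091, hann = 2.0)

#' Transform-limited peak width
#'
#' With zero intrinsic ion width, reconstructed peaks have the shape of the
#' apodisation window's transform, whose half-amplitude main-lobe width
#' scales as `constant / (f_max - f_min)`: 1.2067 for the rectangular
#' window (the sinc main lobe) and exactly 2 for Hann. Wider frequency
#' bands therefore give proportionally sharper drift-time peaks.
#'
#' @param f_min,f_max Band edges, Hz (`f_max > f_min`).
#' @param window `"rectangular"` or `"hann"`.
#' @return Full width at half maximum in ms.
#' @examples
#' ft_limited_fwhm(2, 4000) / ft_limited_fwhm(2, 1000)   # ~1/4
#' @export
ft_limited_fwhm <- function(f_min, f_max, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (any(f_max <= f_min)) abort("`f_max` must exceed `f_min`",
                                 class = "ftims_error_plan")
  1000 * window_fwhm_constant[[window]] / (f_max - f_min)
}

#' Flag probable odd-harmonic artifacts among fitted peaks
#'
#' The 50%-duty gate correlation is triangular, so a true drift time `td`
#' also produces components at odd multiples (`3 td`, `5 td`, ...) with
#' rapidly decreasing amplitude (1/9, 1/25 of the fundamental under a
#' rectangular window). A fitted peak whose centre sits at an odd multiple
#' of a stronger peak's centre (within one resolution bin) and whose height
#' is below 20% of that peak is flagged `possible_harmonic`.
#'
#' @param peaks Peak table from [fit_peaks()].
#' @param spectrum The `ftims_spectrum` the peaks were fitted on (used for
#'   the resolution bin width); alternatively pass `bin_ms` directly.
#' @param bin_ms Matching tolerance in ms; defaults to the spectrum's
#'   resolution bin.
#' @return `peaks` with a logical `possible_harmonic` column.
#' @export
flag_harmonics <- function(peaks, spectrum = NULL, bin_ms = NULL) {
  bin_ms <- bin_ms %||% attr(spectrum, "resolution_bin_ms")
  if (is.null(bin_ms)) {
    abort("supply `spectrum` or `bin_ms` for the matching tolerance",
          class = "ftims_error_peaks")
  }
  flag <- rep(FALSE, nrow(peaks))
  if (nrow(peaks) >= 2) {
    for (j in seq_len(nrow(peaks))) {
      for (i in seq_len(nrow(peaks))) {
        if (i == j || peaks$height[i] <= peaks$height[j]) next
        for (m in c(3, 5)) {
          if (abs(peaks$td[j] - m * peaks$td[i]) <= bin_ms &&
              peaks$height[j] < 0.2 * peaks$height[i]) {
            flag[j] <- TRUE
          }
        }
      }
    }
  }
  peaks$possible_harmonic <- flag
  peaks
}
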