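#' Detect and fit peaks in a mobility spectrum
#'
#' Local maxima whose height exceeds `min_prominence` times the global
#' maximum are each fitted with a Gaussian over a window of +/- 2
#' preliminary half-widths (the preliminary half-width is read off the
#' samples above half height). The full width at half maximum is
#' `2.3548 * sigma` of the fit. Ties in height are resolved in favour of
#' the shortest drift time. The first half drift-time bin is excluded so
#' residual DC cannot masquerade as a peak.
#'
#' @param spectrum An `ftims_spectrum` (or any tibble with `drift_time_ms`
#'   and `intensity`).
#' @param min_prominence Detection threshold as a fraction of the global
#'   maximum (default 0.1).
#' @return Tibble with one row per peak: `td` (ms), `w_half` (fwhm, ms),
#'   `height`, `area` and `converged` (did the nonlinear fit succeed, or
#'   were moment estimates used). Ordered by drift time. Zero rows when
#'   nothing exceeds the threshold.
#' @export
fit_peaks <- function(spectrum, min_prominence = 0.1) {
  x <- spectrum$drift_time_ms
  y <- spectrum$intensity
  if (length(x) < 5) abort("spectrum too short", class = "ftims_error_peaks")
  res_bin <- attr(spectrum, "resolution_bin_ms") %||% (5 * (x[2] - x[1]))
  usable <- x > res_bin / 2          # keep clear of the DC bin
  ymax <- max(y[usable])
  if (!is.finite(ymax) || ymax <= 0) return(empty_peaks())
  thr <- min_prominence * ymax
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE) & usable & y >= thr
  idx <- which(is_max)
  if (!length(idx)) return(empty_peaks())
  # collapse plateaus/shoulders closer than half a resolution bin
  keep <- idx[c(TRUE, diff(x[idx]) > res_bin / 2)]
  # sidelobe suppression: a rectangular window's transform carries ~22%
  # sidelobes around every line, so candidate maxima much weaker than a
  # taller peak within its line-shape footprint are part of that peak's
  # shape, not separate species
  ord <- order(-y[keep], x[keep])
  keep <- keep[ord]
  main <- rep(TRUE, length(keep))
  for (j in seq_along(keep)[-1]) {
    taller <- keep[seq_len(j - 1)][main[seq_len(j - 1)]]
    near <- abs(x[taller] - x[keep[j]]) < 10 * res_bin
    if (any(near & y[keep[j]] < 0.25 * y[taller])) main[j] <- FALSE
  }
  keep <- sort(keep[main])
  peaks <- map(keep, function(i) fit_one_peak(x, y, i)) |> list_rbind()
  # merge duplicates (ripple/shoulder fits landing on the same feature):
  # keep the tallest of any peaks closer than half their width
  ord <- order(-peaks$height, peaks$td)
  kept <- integer()
  for (j in ord) {
    close <- abs(peaks$td[kept] - peaks$td[j]) <
      pmax(res_bin / 2, peaks$w_half[kept] / 2)
    if (!any(close)) kept <- c(kept, j)
  }
  peaks <- peaks[sort(kept), ]
  arrange(peaks, .data$td)
}

empty_peaks <- function() {
  tibble(td = numeric(), w_half = numeric(), height = numeric(),
         area = numeric(), converged = logical())
}

# Gaussian fit around local maximum i; window = +/- 2 preliminary
# half-widths. Falls back to the preliminary (half-height) estimates if
# the nonlinear fit fails.
fit_one_peak <- function(x, y, i) {
  n <- length(x)
  half <- y[i] / 2
  lo <- i
  while (lo > 1 && y[lo - 1] < y[lo] && y[lo] > half) lo <- lo - 1
  hi <- i
  while (hi < n && y[hi + 1] < y[hi] && y[hi] > half) hi <- hi + 1
  above <- which(y >= half)
  lo_h <- i; while (lo_h > 1 && y[lo_h - 1] >= half && lo_h - 1 >= lo) lo_h <- lo_h - 1
  hi_h <- i; while (hi_h < n && y[hi_h + 1] >= half && hi_h + 1 <= hi) hi_h <- hi_h + 1
  # interpolated half-height crossings
  xl <- if (lo_h > 1) interp_cross(x[lo_h - 1], x[lo_h], y[lo_h - 1], y[lo_h], half) else x[1]
  xr <- if (hi_h < n) interp_cross(x[hi_h + 1], x[hi_h], y[hi_h + 1], y[hi_h], half) else x[n]
  w_prelim <- max(xr - xl, x[2] - x[1])
  win <- x >= x[i] - 2 * w_prelim & x <= x[i] + 2 * w_prelim
  xw <- x[win]; yw <- y[win]
  start <- list(h = y[i], c = x[i], s = w_prelim / 2.3548)
  fit <- tryCatch(
    minpack.lm::nlsLM(yw ~ h * exp(-(xw - c)^2 / (2 * s^2)),
                      start = start,
                      lower = c(h = 0, c = min(xw), s = 1e-9),
                      upper = c(h = 2 * max(yw), c = max(xw),
                                s = max(xw) - min(xw)),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  moment <- tibble(td = x[i], w_half = w_prelim, height = y[i],
                   area = y[i] * w_prelim / 2.3548 * sqrt(2 * pi),
                   converged = FALSE)
  if (is.null(fit)) return(moment)
  p <- coef(fit)
  s <- abs(p[["s"]])
  # reject fits that wandered off the detected feature
  if (abs(p[["c"]] - x[i]) > w_prelim || 2.3548 * s > 3 * w_prelim ||
      p[["h"]] > 1.9 * max(yw)) {
    return(moment)
  }
  tibble(td = p[["c"]], w_half = 2.3548 * s, height = p[["h"]],
         area = p[["h"]] * s * sqrt(2 * pi), converged = TRUE)
}

interp_cross <- function(x0, x1, y0, y1, level) {
  if (y1 == y0) return(x1)
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}

#' Resolving power of a peak
#'
#' `Rp = td / w_half`: drift time over full width at half maximum,
#' dimensionless. Given a peak table, appends an `rp` column; given
#' numeric vectors, returns the values.
#'
#' @param td Drift time(s) in ms, or a peak table from [fit_peaks()].
#' @param w_half Full width(s) at half maximum, ms (ignored when `td` is a
#'   peak table).
#' @return Numeric resolving power(s), or the peak table with an `rp`
#'   column.
#' @examples
#' resolving_power(36.67, 0.4371)   # 83.9
#' @export
resolving_power <- function(td, w_half = NULL) {
  if (is.data.frame(td)) {
    peaks <- td
    peaks$rp <- resolving_power(peaks$td, peaks$w_half)
    return(peaks)
  }
  if (any(w_half <= 0)) {
    abort("resolving power is undefined for non-positive width",
          class = "ftims_error_peaks")
  }
  td / w_half
}

#' Root-mean-square noise of an intensity series
#'
#' Population RMS deviation about the arithmetic mean:
#' `sqrt(sum((H - mean(H))^2) / n)`. Set `ddof = 1` for the sample
#' (n - 1) convention.
#'
#' @param H Intensity values (length >= 2).
#' @param ddof Delta degrees of freedom (0 = population, default).
#' @return The RMS noise (scalar).
#' @examples
#' rms_noise(c(1, 2, 3, 4, 5))   # sqrt(2)
#' @export
rms_noise <- function(H, ddof = 0) {
  n <- length(H)
  if (n < 2) abort("RMS noise needs at least 2 points",
                   class = "ftims_error_noise")
  sqrt(sum((H - mean(H))^2) / (n - ddof))
}

#' Noise estimate over a spectral region
#'
#' @param spectrum An `ftims_spectrum`.
#' @param region Length-2 numeric `(start, end)` drift-time window in ms.
#' @param ddof Passed to [rms_noise()].
#' @return One-row tibble: `mu_rms`, `start`, `end`, `n`.
#' @export
noise_estimate <- function(spectrum, region, ddof = 0) {
  keep <- spectrum$drift_time_ms >= region[1] &
    spectrum$drift_time_ms <= region[2]
  if (sum(keep) < 2) {
    abort("noise region contains fewer than 2 points",
          class = "ftims_error_noise")
  }
  tibble(mu_rms = rms_noise(spectrum$intensity[keep], ddof),
         start = region[1], end = region[2], n = sum(keep))
}

# default noise window: the last 20% of the drift axis, slid earlier in
# 10%-of-axis steps until it clears every peak by 3 half-widths
default_noise_region <- function(spectrum, peaks) {
  td_max <- max(spectrum$drift_time_ms)
  len <- 0.2 * td_max
  start <- td_max - len
  while (start >= 0) {
    region <- c(start, start + len)
    if (!region_overlaps_peaks(region, peaks)) return(region)
    start <- start - 0.1 * td_max
  }
  abort("could not find a peak-free noise region; supply one explicitly",
        class = "ftims_error_noise")
}

region_overlaps_peaks <- function(region, peaks) {
  if (nrow(peaks) == 0) return(FALSE)
  any(peaks$td + 3 * peaks$w_half >= region[1] &
        peaks$td - 3 * peaks$w_half <= region[2])
}

#' Signal-to-noise ratios of fitted peaks
#'
#' `S/N = peak height / mu_rms` with the RMS noise measured over a
#' peak-free region of the spectrum. By default the region is the final
#' 20% of the drift axis, slid earlier if a peak (within +/- 3 fwhm)
#' intrudes; an explicitly supplied region that overlaps a peak is
#' refused. A noiseless region gives `Inf`.
#'
#' @param spectrum An `ftims_spectrum`.
#' @param peaks Peak table from [fit_peaks()].
#' @param noise_region Optional `(start, end)` ms window.
#' @param ddof Passed to [rms_noise()].
#' @return `peaks` with an `snr` column; the noise estimate is attached as
#'   attribute `"noise"`.
#' @export
snr <- function(spectrum, peaks, noise_region = NULL, ddof = 0) {
  if (nrow(peaks) == 0) {
    peaks$snr <- numeric()
    return(peaks)
  }
  if (is.null(noise_region)) {
    noise_region <- default_noise_region(spectrum, peaks)
  } else if (region_overlaps_peaks(noise_region, peaks)) {
    abort("noise region overlaps a fitted peak (within 3 half-widths); choose another",
          class = "ftims_error_noise")
  }
  est <- noise_estimate(spectrum, noise_region, ddof)
  peaks$snr <- if (est$mu_rms == 0) Inf else peaks$height / est$mu_rms
  attr(peaks, "noise") <- est
  peaks
}

#' Full spectral report: peaks, mobility, resolving power, S/N
#'
#' Convenience wrapper chaining [fit_peaks()], [resolving_power()],
#' [reduced_mobility()], [snr()] and [flag_harmonics()].
#'
#' @param spectrum An `ftims_spectrum`.
#' @param cell A [drift_cell()] for the K0 column.
#' @param min_prominence Passed to [fit_peaks()].
#' @param noise_region Passed to [snr()].
#' @return Peak table with columns `td`, `w_half`, `height`, `area`,
#'   `rp`, `K0`, `snr`, `possible_harmonic`; noise estimate in attribute
#'   `"noise"`.
#' @export
analyze_spectrum <- function(spectrum, cell = drift_cell(),
                             min_prominence = 0.1, noise_region = NULL) {
  peaks <- fit_peaks(spectrum, min_prominence)
  if (nrow(peaks) == 0) {
    out <- peaks
    out$rp <- numeric(); out$K0 <- numeric(); out$snr <- numeric()
    out$possible_harmonic <- logical()
    return(out)
  }
  peaks <- resolving_power(peaks)
  peaks$K0 <- reduced_mobility(peaks$td, cell)
  peaks <- snr(spectrum, peaks, noise_region)
  noise <- attr(peaks, "noise")
  peaks <- flag_harmonics(peaks, spectrum)
  attr(peaks, "noise") <- noise
  peaks
}
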