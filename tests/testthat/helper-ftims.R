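# Independent oracles and fixture builders used across the suite.

# Exact circular overlap of two duty-d square gate waveforms offset by a
# delay td (ms) at frequency f (Hz), computed by interval intersection on
# one period -- independent of the closed-form triangle expression.
oracle_overlap <- function(f, td, duty = 0.5) {
  period <- 1 / f
  delay <- (td * 1e-3) %% period
  # gate A open on [0, duty*period); gate B open on [delay, delay+duty*period)
  a <- c(0, duty * period)
  b_start <- delay
  b_end <- delay + duty * period
  segs <- if (b_end <= period) {
    list(c(b_start, b_end))
  } else {
    list(c(b_start, period), c(0, b_end - period))
  }
  overlap <- sum(vapply(segs, function(s) {
    max(0, min(a[2], s[2]) - max(a[1], s[1]))
  }, numeric(1)))
  overlap / period
}

# Grid-sampled overlap integral (numerical brute force).
oracle_overlap_grid <- function(f, td, duty = 0.5, n = 2e5) {
  t <- (seq_len(n) - 0.5) / n / f
  a <- ((t * f) %% 1) < duty
  b <- (((t - td * 1e-3) * f) %% 1) < duty
  mean(a & b)
}

# Minimal mobility-spectrum object from bare vectors.
make_spectrum <- function(drift_time_ms, intensity, resolution_bin_ms = NULL) {
  out <- tibble::tibble(drift_time_ms = drift_time_ms, intensity = intensity)
  class(out) <- c("ftims_spectrum", class(out))
  if (is.null(resolution_bin_ms)) {
    resolution_bin_ms <- 5 * (drift_time_ms[2] - drift_time_ms[1])
  }
  attr(out, "resolution_bin_ms") <- resolution_bin_ms
  out
}

# Random ion mixture with a minimum drift-time separation.
random_mixture <- function(n_ion, td_range = c(15, 46), min_sep = 3,
                          sigma = 0) {
  repeat {
    td <- sort(runif(n_ion, td_range[1], td_range[2]))
    if (n_ion == 1 || min(diff(td)) > min_sep) break
  }
  ab <- runif(n_ion, 0.5, 1)
  dplyr::bind_rows(lapply(seq_len(n_ion), function(i) {
    ion_species(paste0("ion", i), td = td[i], abundance = ab[i], sigma = sigma)
  }))
}

# Amplitude of the interferogram's Fourier component at conjugate time
# t0_ms, by direct DFT (not via reconstruct_spectrum).
component_amplitude <- function(ig, t0_ms) {
  x <- ig$signal - mean(ig$signal)
  f <- ig$frequency_hz
  2 * Mod(sum(x * exp(-2i * pi * f * t0_ms * 1e-3))) / length(x)
}

# Half-amplitude width of a window's transform main lobe, in units of
# 1/bandwidth, via heavily zero-padded FFT of the window itself.
oracle_window_fwhm_constant <- function(w) {
  n <- length(w)
  nf <- 2^18
  X <- Mod(stats::fft(c(w, rep(0, nf - n))))
  X <- X / X[1]
  k <- which(X[seq_len(nf / 4)] < 0.5)[1]
  frac <- (X[k - 1] - 0.5) / (X[k - 1] - X[k])
  2 * (k - 2 + frac) / nf * n
}

# Interpolated full width at half maximum around the global maximum of a
# spectrum (direct crossing measurement, no model fit).
measured_fwhm <- function(spectrum) {
  x <- spectrum$drift_time_ms
  y <- spectrum$intensity
  i <- which.max(y)
  half <- y[i] / 2
  lo <- i; while (lo > 1 && y[lo] > half) lo <- lo - 1
  hi <- i; while (hi < length(y) && y[hi] > half) hi <- hi + 1
  xl <- x[lo] + (half - y[lo]) / (y[lo + 1] - y[lo]) * (x[lo + 1] - x[lo])
  xr <- x[hi - 1] + (half - y[hi - 1]) / (y[hi] - y[hi - 1]) * (x[hi] - x[hi - 1])
  xr - xl
}
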