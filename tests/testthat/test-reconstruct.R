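cosine_interferogram <- function(td_ms, f_min = 10, f_step = 5, f_max = 4000,
                                 amp = 1) {
  f <- seq(f_min, f_max, by = f_step)
  ftims:::new_interferogram(f, amp * cos(2 * pi * f * td_ms * 1e-3),
                            meta = list(f_step = f_step))
}

test_that("a pure cosine reconstructs to a single peak at its conjugate time", {
  ig <- cosine_interferogram(30)
  sp <- reconstruct_spectrum(ig)
  bin <- attr(sp, "resolution_bin_ms")
  expect_equal(sp$drift_time_ms[which.max(sp$intensity)], 30, tolerance = bin)
  expect_equal(max(sp$intensity), 1, tolerance = 0.01)   # unit amplitude
  expect_true(all(sp$intensity >= 0))
  # maximum representable drift time is 1/(2 f_step)
  expect_equal(max(sp$drift_time_ms), 100, tolerance = attr(sp, "bin_ms"))
  # a constant interferogram is annihilated by the detrend
  flat <- ftims:::new_interferogram(ig$frequency_hz,
                                    rep(2.5, nrow(ig)),
                                    meta = list(f_step = 5))
  expect_lt(max(reconstruct_spectrum(flat)$intensity), 1e-9 * max(sp$intensity))
})

test_that("the triangular gate correlation yields a 1/9 harmonic artifact", {
  ion <- ion_species("x", td = 30, sigma = 0)
  ig <- simulate_interferogram(plan_stepped(2, 2, 4000, 1), ion)
  sp <- reconstruct_spectrum(ig)
  pk <- fit_peaks(sp, 0.05)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$td, c(30, 90), tolerance = 0.01)
  expect_equal(pk$height[2] / pk$height[1], 1 / 9, tolerance = 0.05)
  flagged <- flag_harmonics(pk, sp)
  expect_identical(flagged$possible_harmonic, c(FALSE, TRUE))
})

test_that("harmonic flagging ignores single peaks and non-odd-multiple pairs", {
  single <- tibble::tibble(td = 30, w_half = 0.3, height = 1)
  expect_false(any(flag_harmonics(single, bin_ms = 0.25)$possible_harmonic))
  pair <- tibble::tibble(td = c(30, 45), w_half = 0.3, height = c(1, 0.1))
  expect_false(any(flag_harmonics(pair, bin_ms = 0.25)$possible_harmonic))
  # a 30/90 pair at 11% is flagged; at 30% (a genuine species) it is not
  art <- tibble::tibble(td = c(30, 90), w_half = 0.3, height = c(1, 0.11))
  expect_identical(flag_harmonics(art, bin_ms = 0.25)$possible_harmonic,
                   c(FALSE, TRUE))
  genuine <- tibble::tibble(td = c(30, 90), w_half = 0.3, height = c(1, 0.3))
  expect_false(any(flag_harmonics(genuine, bin_ms = 0.25)$possible_harmonic))
})

test_that("transform-limited widths scale inversely with bandwidth", {
  expect_equal(ft_limited_fwhm(2, 4000) / ft_limited_fwhm(2, 1000),
               998 / 3998)
  # monotone shrinkage towards broad bands
  bands <- c(500, 1000, 2000, 4000, 8000)
  expect_true(all(diff(ft_limited_fwhm(2, bands)) < 0))
  # the per-window constants against brute-force transforms of the windows
  n <- 4096
  rect_const <- oracle_window_fwhm_constant(rep(1, n))
  hann_const <- oracle_window_fwhm_constant(
    0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_equal(ft_limited_fwhm(0, 1000), rect_const, tolerance = 1e-3)
  expect_equal(ft_limited_fwhm(0, 1000, "hann"), hann_const, tolerance = 1e-3)
})

test_that("measured cosine peak widths match the closed form within 2%", {
  for (band in list(c(10, 1000), c(10, 4000))) {
    ig <- cosine_interferogram(30, f_min = band[1], f_max = band[2])
    sp <- reconstruct_spectrum(ig, zero_pad_factor = 8)
    expect_equal(measured_fwhm(sp), ft_limited_fwhm(band[1], band[2]),
                 tolerance = 0.02)
    sph <- reconstruct_spectrum(ig, "hann", zero_pad_factor = 8)
    expect_equal(measured_fwhm(sph),
                 ft_limited_fwhm(band[1], band[2], "hann"),
                 tolerance = 0.02)
  }
})

test_that("peak centres of random mixtures are recovered to within one bin", {
  plan <- plan_stepped(10, 5, 4000, 4)
  withr::with_seed(301, {
    for (i in 1:20) {
      mix <- random_mixture(sample(1:4, 1))
      ig <- simulate_interferogram(plan, mix)
      sp <- reconstruct_spectrum(ig)
      pk <- fit_peaks(sp, 0.12)
      bin <- attr(sp, "resolution_bin_ms")
      for (td in mix$td) {
        expect_lt(min(abs(pk$td - td)), bin)
      }
    }
  })
})

test_that("noisy mixtures (spectral S/N near 10) are recovered in >= 95% of trials", {
  plan <- plan_stepped(10, 5, 4000, 4)
  n_trials <- 100
  hits <- withr::with_seed(302, {
    vapply(seq_len(n_trials), function(i) {
      mix <- random_mixture(sample(1:4, 1))
      ig <- simulate_interferogram(plan, mix,
                                   noise = noise_model(white_rms = 0.3,
                                                       seed = 5000 + i))
      sp <- reconstruct_spectrum(ig)
      pk <- fit_peaks(sp, 0.12)
      bin <- attr(sp, "resolution_bin_ms")
      nrow(pk) > 0 &&
        all(vapply(mix$td, function(td) min(abs(pk$td - td)) < 2 * bin,
                   logical(1)))
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("resolving power grows linearly with bandwidth for width-free ions", {
  ion <- ion_species("x", td = 30, sigma = 0)
  bands <- c(500, 1000, 2000, 4000)
  rp <- vapply(bands, function(fm) {
    ig <- simulate_interferogram(plan_stepped(2, 2, fm, 1), ion)
    sp <- reconstruct_spectrum(ig)
    pk <- resolving_power(fit_peaks(sp, 0.2))
    pk$rp[which.max(pk$height)]
  }, numeric(1))
  fit <- stats::lm(rp ~ I(bands - 2))
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("adding an ion never decreases total spectral magnitude", {
  plan <- plan_stepped(10, 5, 2000, 1)
  one <- simulate_interferogram(plan, ion_species("a", td = 25, sigma = 0.1))
  two <- simulate_interferogram(
    plan, ion_mixture(ion_species("a", td = 25, sigma = 0.1),
                      ion_species("b", td = 38, sigma = 0.1)))
  expect_gte(sum(reconstruct_spectrum(two)$intensity),
             sum(reconstruct_spectrum(one)$intensity))
})

test_that("non-uniform frequency grids are refused with resampling guidance", {
  f <- c(seq(10, 500, by = 5), 517)
  bad <- tibble::tibble(frequency_hz = f, signal = rnorm(length(f)))
  expect_error(reconstruct_spectrum(bad), "resample",
               class = "ftims_error_interferogram")
})
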