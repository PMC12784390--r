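test_that("steady-state interferogram equals the analytic gate correlation", {
  cell <- drift_cell(C = 43.12)
  plan <- plan_stepped(12.5, 12.5, 50, 1)
  # one ion, quarter phase at 12.5 Hz for td = 20 ms -> 0.25 above baseline
  ion <- ion_species("x", td = 20, sigma = 0)
  ig <- simulate_interferogram(plan, ion, cell,
                               noise_model(baseline = 0.1))
  expect_equal(ig$signal[1], 0.1 + 0.25)
  expect_equal(ig$signal[ig$frequency_hz == 50], 0.1 + 0.5)
  # no ions, zero baseline, no noise: identically zero
  empty <- simulate_interferogram(plan, ion_mixture(), cell)
  expect_true(all(empty$signal == 0))
})

test_that("the steady-state signal is linear in the mixture", {
  cell <- drift_cell()
  plan <- plan_stepped(10, 10, 2000, 1)
  a <- ion_species("a", td = 22, sigma = 0.2, abundance = 0.7)
  b <- ion_species("b", td = 35, sigma = 0.1, abundance = 1.3)
  both <- simulate_interferogram(plan, ion_mixture(a, b), cell)
  one <- simulate_interferogram(plan, a, cell)
  two <- simulate_interferogram(plan, b, cell)
  expect_equal(both$signal, one$signal + two$signal, tolerance = 1e-12)
})

test_that("noise streams are seed-deterministic with index-stable substreams", {
  plan <- plan_stepped(10, 10, 500, 1)
  nm <- noise_model(white_rms = 0.5, seed = 42)
  ig1 <- simulate_interferogram(plan, ion_mixture(), noise = nm)
  ig2 <- simulate_interferogram(plan, ion_mixture(), noise = nm)
  expect_identical(ig1$signal, ig2$signal)
  expect_false(identical(
    ig1$signal,
    simulate_interferogram(plan, ion_mixture(),
                           noise = noise_model(0.5, seed = 43))$signal))
  # shortening the plan leaves the shared leading steps' draws unchanged
  short <- simulate_interferogram(plan_stepped(10, 10, 200, 1),
                                  ion_mixture(), noise = nm)
  expect_identical(short$signal, ig1$signal[1:20])
})

test_that("time-domain windowed means match the steady-state oracle", {
  cell <- drift_cell()
  # pass-through amplifier, whole-period windows: within 1%
  withr::with_seed(202, {
    for (i in 1:20) {
      repeat {
        f <- runif(1, 50, 500)
        td <- runif(1, 15, 45)
        g <- gate_correlation(f, td)
        if (g >= 0.1) break
      }
      ion <- ion_species("x", td = td, sigma = 0)
      step <- tibble::tibble(f = f, dwell = 10 / f, trigger_offset = 0)
      rec <- simulate_time_domain(step, ion, cell, amplifier(rise_time = 0),
                                  sample_rate = 2000 * f)
      expect_equal(record_mean(rec, 0, whole_periods = TRUE), g,
                   tolerance = 0.01)
    }
  })
  # slow amplifier (~30 gate periods), arbitrary offsets: within 2%
  withr::with_seed(203, {
    for (i in 1:8) {
      repeat {
        f <- runif(1, 200, 800)
        td <- runif(1, 15, 45)
        g <- gate_correlation(f, td)
        if (g >= 0.1) break
      }
      ion <- ion_species("x", td = td, sigma = 0)
      step <- tibble::tibble(f = f, dwell = 200 / f, trigger_offset = 0)
      rec <- simulate_time_domain(step, ion, cell,
                                  amplifier(rise_time = 1000 * 30 / f),
                                  sample_rate = 400 * f)
      expect_equal(record_mean(rec, runif(1, 0, 1 / f)), g, tolerance = 0.02)
    }
  })
})

test_that("a long amplifier rise time makes the data window placement irrelevant", {
  # the asynchronous-triggering claim: with rise time >= 10 gate periods the
  # windowed mean varies by < 1% across trigger offsets spanning a period
  cell <- drift_cell()
  f <- 400
  ion <- ion_species("x", td = 22, sigma = 0)
  step <- tibble::tibble(f = f, dwell = 200 / f, trigger_offset = 0)
  rec <- simulate_time_domain(step, ion, cell,
                              amplifier(rise_time = 1000 * 30 / f),
                              sample_rate = 400 * f)
  offsets <- seq(0, 1 / f, length.out = 20)
  means <- vapply(offsets, function(o) record_mean(rec, o), numeric(1))
  expect_lt(sd(means) / mean(means), 0.01)
  # without the slow amplifier the window placement matters visibly
  fast <- simulate_time_domain(step, ion, cell, amplifier(rise_time = 0),
                               sample_rate = 400 * f)
  fast_means <- vapply(offsets, function(o) record_mean(fast, o), numeric(1))
  expect_gt(sd(fast_means) / mean(fast_means), sd(means) / mean(means))
})

test_that("zero-abundance ions reduce the record to the filtered baseline", {
  ion <- ion_species("x", td = 20, abundance = 0, sigma = 0)
  step <- tibble::tibble(f = 100, dwell = 0.1, trigger_offset = 0)
  rec <- simulate_time_domain(step, ion, drift_cell(),
                              amplifier(rise_time = 50),
                              noise_model(baseline = 0.3), sample_rate = 5000)
  expect_equal(rec$signal, rep(0.3, nrow(rec)), tolerance = 1e-12)
})

test_that("single-gate traces peak at the drift time with averaging-law noise", {
  plan <- plan_single_gate(50, 0.2, 275)
  ion <- ion_species("x", td = 30, sigma = 0.15)
  tr <- simulate_single_gate(plan, ion, amp = amplifier(rise_time = 0))
  dt <- tr$time_ms[2] - tr$time_ms[1]
  expect_equal(tr$time_ms[which.max(tr$signal)], 30, tolerance = dt + 1e-12)
  # no ions: flat baseline
  flat <- simulate_single_gate(plan, ion_mixture(),
                               noise = noise_model(baseline = 0.2))
  expect_true(all(abs(flat$signal - 0.2) < 1e-12))
  # residual noise shrinks as 1/sqrt(n_scans)
  nm <- noise_model(white_rms = 1, seed = 5)
  many <- simulate_single_gate(plan, ion_mixture(), amp = amplifier(rise_time = 0),
                               noise = nm)
  single <- simulate_single_gate(plan_single_gate(50, 0.2, 1), ion_mixture(),
                                 amp = amplifier(rise_time = 0), noise = nm)
  ratio <- sd(many$signal) / sd(single$signal)
  expect_equal(ratio * sqrt(275), 1, tolerance = 0.2)
})

test_that("swept records carry the chirp and match stepped reconstructions", {
  mix <- ion_mixture(ion_species("a", td = 24, sigma = 0.1),
                     ion_species("b", td = 33, sigma = 0.1))
  plan <- plan_swept(4, 4000, 8)
  rec <- simulate_swept(plan, mix, sample_rate = 2000)
  # single ion: oscillation bounded by the duty ceiling, frequency axis linear
  expect_true(all(rec$signal >= 0 & rec$signal <= 1.01))
  # empty mixture -> baseline
  base <- simulate_swept(plan, ion_mixture(),
                         noise = noise_model(baseline = 0.4),
                         sample_rate = 500)
  expect_true(all(base$signal == 0.4))
  # swept and stepped reconstructions agree within one resolution bin
  sw_sp <- reconstruct_spectrum(swept_to_interferogram(rec, 5))
  st_sp <- reconstruct_spectrum(
    simulate_interferogram(plan_stepped(4, 5, 4000, 4), mix))
  sw_pk <- fit_peaks(sw_sp, 0.3)
  st_pk <- fit_peaks(st_sp, 0.3)
  expect_equal(nrow(sw_pk), 2)
  expect_equal(nrow(st_pk), 2)
  bin <- attr(st_sp, "resolution_bin_ms")
  expect_lt(max(abs(sw_pk$td - st_pk$td)), bin)
})

test_that("undersampled simulations are refused", {
  step <- tibble::tibble(f = 1000, dwell = 0.1, trigger_offset = 0)
  expect_error(
    simulate_time_domain(step, ion_mixture(), sample_rate = 5000),
    class = "ftims_error_sampling")
  expect_error(
    simulate_interferogram(plan_swept(4, 100, 1), ion_mixture()),
    class = "ftims_error_plan")
})
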