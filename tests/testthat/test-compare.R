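test_that("percent increase reproduces the benchmark improvement figures", {
  expect_equal(round(percent_increase(55, 80)), 45)
  expect_equal(round(percent_increase(4.3, 10.2)), 137)
  expect_equal(percent_increase(7, 7), 0)
  expect_error(percent_increase(0, 5), class = "ftims_error_compare")
  # forward and inverse changes compose to the identity
  withr::with_seed(3, { a <- runif(50, 1, 100); b <- runif(50, 1, 100) })
  p <- percent_increase(a, b)
  q <- percent_increase(b, a)
  expect_equal((1 + p / 100) * (1 + q / 100), rep(1, 50))
})

test_that("the comparison report reproduces the 21% ratio-of-means Rp gain", {
  rep9 <- build_report(reference_compounds())
  s <- glance(rep9)
  expect_equal(round(s$pct_rp_increase), 21)
  expect_equal(s$mean_rp_sg, 64.04111, tolerance = 1e-6)
  expect_equal(s$mean_rp_ft, 77.67, tolerance = 1e-6)
  # a single-compound report: the cocaine-style 55 -> 80 pair
  one <- build_report(tibble::tibble(compound = "x", rp_sg = 55, rp_ft = 80,
                                     snr_sg = 1, snr_ft = 1))
  expect_equal(round(glance(one)$pct_rp_increase), 45)
  # identical columns -> 0% everywhere
  same <- build_report(tibble::tibble(rp_sg = c(10, 20), rp_ft = c(10, 20),
                                      snr_sg = c(1, 2), snr_ft = c(1, 2)))
  expect_equal(glance(same)$pct_rp_increase, 0)
  expect_equal(glance(same)$pct_snr_increase, 0)
  # tidy() returns the rows; missing columns are refused
  expect_equal(nrow(tidy(rep9)), 9)
  expect_error(build_report(tibble::tibble(rp_sg = 1)),
               class = "ftims_error_compare")
})

test_that("the summary uses ratio of column means, not mean of row ratios", {
  ref <- reference_compounds()
  row_wise <- mean(percent_increase(ref$rp_sg, ref$rp_ft))
  col_wise <- glance(build_report(ref))$pct_rp_increase
  expect_gt(row_wise, 28)          # the readings genuinely differ
  expect_equal(round(col_wise), 21)
})

test_that("paired deltas carry the per-compound differences and t statistic", {
  ref <- reference_compounds()
  ps <- paired_delta_summary(build_report(ref))
  expect_equal(nrow(ps$deltas), 9)
  expect_equal(ps$deltas$delta[ps$deltas$compound == "DtBP"], 42.20)
  expect_equal(ps$mean, mean(ref$rp_ft - ref$rp_sg))
  expect_gt(ps$t, 2)               # a significant FT-mode gain
  expect_lt(ps$p_value, 0.05)
  # identical columns: all deltas zero, t = 0
  same <- tibble::tibble(compound = c("a", "b"), rp_sg = c(5, 7),
                         rp_ft = c(5, 7), snr_sg = 1:2, snr_ft = 1:2)
  ps0 <- paired_delta_summary(build_report(same))
  expect_equal(ps0$deltas$delta, c(0, 0))
  expect_equal(ps0$t, 0)
  # symmetric +1/-1 deltas average to zero
  sym <- tibble::tibble(compound = c("a", "b"), rp_sg = c(5, 7),
                        rp_ft = c(6, 6), snr_sg = 1:2, snr_ft = 1:2)
  expect_equal(paired_delta_summary(build_report(sym))$mean, 0)
  expect_error(paired_delta_summary(build_report(same[1, ])),
               class = "ftims_error_compare")
})

test_that("final-frequency studies show the fourfold resolving-power gain", {
  ion <- ion_species("x", td = 30, sigma = 0)
  tab <- run_frequency_study("f_max", c(1000, 4000), ion,
                             fixed = list(f_min = 2, f_step = 2, n_avg = 1),
                             replicates = 1)
  expect_equal(tab$mean_rp[2] / tab$mean_rp[1], 4, tolerance = 0.02)
  expect_false(any(tab$flagged))
})

test_that("start frequency and step size barely move Rp while time scales with steps", {
  rip <- fixture_mixture("rip")
  fmin_tab <- run_frequency_study("f_min", c(2, 4, 6, 8, 10), rip$ions,
                                  rip$cell,
                                  fixed = list(f_step = 2, f_max = 2000,
                                               n_avg = 1),
                                  replicates = 1)
  spread <- (max(fmin_tab$mean_rp) - min(fmin_tab$mean_rp)) /
    mean(fmin_tab$mean_rp)
  expect_lt(spread, 0.05)
  fstep_tab <- run_frequency_study("f_step", 1:5, rip$ions, rip$cell,
                                   fixed = list(f_min = 10, f_max = 2000,
                                                n_avg = 1),
                                   replicates = 1)
  spread2 <- (max(fstep_tab$mean_rp) - min(fstep_tab$mean_rp)) /
    mean(fstep_tab$mean_rp)
  expect_lt(spread2, 0.05)
  # acquisition time tracks the step count (inverse in the step size)
  expect_equal(fstep_tab$duration_s / fstep_tab$duration_s[5],
               fstep_tab$n_steps / fstep_tab$n_steps[5])
  expect_gt(fstep_tab$n_steps[1] / fstep_tab$n_steps[5], 4.9)
})

test_that("study runners are seed-deterministic with zero spread when noise is off", {
  rip <- fixture_mixture("rip")
  nm <- noise_model(white_rms = 0.2, seed = 77)
  t1 <- run_frequency_study("f_max", c(1000, 2000), rip$ions, rip$cell,
                            fixed = list(f_min = 10, f_step = 5, n_avg = 1),
                            noise = nm, replicates = 2)
  t2 <- run_frequency_study("f_max", c(1000, 2000), rip$ions, rip$cell,
                            fixed = list(f_min = 10, f_step = 5, n_avg = 1),
                            noise = nm, replicates = 2)
  expect_identical(t1$mean_rp, t2$mean_rp)
  expect_true(all(t1$sd_rp > 0))
  quiet <- run_frequency_study("f_max", c(1000, 2000), rip$ions, rip$cell,
                               fixed = list(f_min = 10, f_step = 5, n_avg = 1),
                               replicates = 3)
  expect_equal(quiet$sd_rp, c(0, 0))
})
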