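#' Benchmark single-gate vs stepped-FT measurements
#'
#' Bundled instrument measurements for nine common IMS standards and
#' analytes, each measured on the same drift cell in pulsed single-gate
#' (SG) mode and in stepped dual-gate FT mode: drift time (ms), reduced
#' mobility (cm^2 V^-1 s^-1), resolving power and signal-to-noise ratio
#' per mode, plus literature reduced mobilities. The tetraalkylammonium
#' rows (T3A--T6A) double as mobility standards for the default
#' calibration constant of [drift_cell()].
#'
#' @return Tibble with columns `compound`, `td_sg`, `k0_sg`, `rp_sg`,
#'   `snr_sg`, `td_ft`, `k0_ft`, `rp_ft`, `snr_ft`, `k0_lit`.
#' @export
reference_compounds <- function() {
  tibble::tribble(
    ~compound,      ~td_sg, ~k0_sg, ~rp_sg, ~snr_sg, ~td_ft, ~k0_ft, ~rp_ft, ~snr_ft, ~k0_lit,
    "DtBP",          30.34,   1.42,  38.35,    5.69,  30.27,   1.41,  80.55,   16.82,    1.42,
    "DMMP (Dimer)",  30.52,   1.41,  63.91,    3.16,  31.00,   1.39,  76.80,    6.60,    1.40,
    "Cocaine",       36.71,   1.16,  64.55,    9.13,  36.67,   1.16,  83.90,   17.52,    1.16,
    "T3A",           30.11,   1.43,  71.62,    4.72,  30.00,   1.44,  88.12,    9.20,    1.51,
    "T4A",           35.06,   1.23,  77.89,    5.14,  35.09,   1.23,  78.96,   11.51,    1.28,
    "T5A",           40.33,   1.07,  82.73,    6.16,  40.18,   1.07,  87.86,    8.08,    1.10,
    "T6A",           45.49,   0.95,  84.61,    6.88,  45.53,   0.95,  86.85,    6.55,    0.97,
    "NG",            24.93,   1.71,  54.00,    4.18,  24.70,   1.72,  48.07,   13.47,    1.83,
    "TNT",           28.78,   1.48,  38.71,    3.52,  28.42,   1.50,  67.92,    8.73,    1.54
  )
}

#' Percent increase from `a` to `b`
#'
#' `100 * (b - a) / a`, unrounded (round only for display).
#'
#' @param a Baseline value(s), > 0.
#' @param b New value(s).
#' @return Percent change(s).
#' @examples
#' percent_increase(55, 80)      # 45.45...
#' percent_increase(4.3, 10.2)   # 137.2...
#' @export
percent_increase <- function(a, b) {
  if (any(a <= 0)) abort("percent increase is undefined for baseline <= 0",
                         class = "ftims_error_compare")
  100 * (b - a) / a
}

#' Summarise single-gate vs FT metrics into a comparison report
#'
#' Column means of resolving power and S/N are computed per mode and the
#' overall percent increases are taken as the *ratio of column means*
#' (not the mean of per-row ratios).
#'
#' @param rows Tibble with at least `rp_sg`, `rp_ft`, `snr_sg`, `snr_ft`
#'   (and typically `compound` and drift times), e.g.
#'   [reference_compounds()].
#' @return An object of class `ftims_comparison`; see [tidy()] for the
#'   per-compound rows and [glance()] for the summary.
#' @examples
#' glance(build_report(reference_compounds()))
#' @export
build_report <- function(rows) {
  need <- c("rp_sg", "rp_ft", "snr_sg", "snr_ft")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    abort(paste0("comparison rows are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ftims_error_compare")
  }
  if (nrow(rows) < 1) abort("need at least one row",
                            class = "ftims_error_compare")
  summary <- tibble(
    n = nrow(rows),
    mean_rp_sg = mean(rows$rp_sg),
    mean_rp_ft = mean(rows$rp_ft),
    pct_rp_increase = percent_increase(mean(rows$rp_sg), mean(rows$rp_ft)),
    mean_snr_sg = mean(rows$snr_sg),
    mean_snr_ft = mean(rows$snr_ft),
    pct_snr_increase = percent_increase(mean(rows$snr_sg), mean(rows$snr_ft))
  )
  structure(list(rows = as_tibble(rows), summary = summary),
            class = "ftims_comparison")
}

#' @export
print.ftims_comparison <- function(x, ...) {
  cat(sprintf(
    "<SG vs FT comparison: %d compounds; Rp %.2f -> %.2f (%+.0f%%); S/N %.2f -> %.2f (%+.0f%%)>\n",
    x$summary$n, x$summary$mean_rp_sg, x$summary$mean_rp_ft,
    x$summary$pct_rp_increase, x$summary$mean_snr_sg, x$summary$mean_snr_ft,
    x$summary$pct_snr_increase))
  invisible(x)
}

#' Paired per-compound differences and t statistic
#'
#' Computes `rp_ft - rp_sg` per compound with mean, standard deviation and
#' the paired t statistic. The p-value is returned as descriptive output.
#'
#' @param report An `ftims_comparison` from [build_report()], or a rows
#'   tibble with `rp_sg` and `rp_ft` (>= 2 rows).
#' @return List with `deltas` (tibble `compound`, `delta`), `mean`, `sd`,
#'   `t`, `df`, `p_value`.
#' @export
paired_delta_summary <- function(report) {
  rows <- if (inherits(report, "ftims_comparison")) report$rows else report
  if (nrow(rows) < 2) abort("paired summary needs at least 2 rows",
                            class = "ftims_error_compare")
  delta <- rows$rp_ft - rows$rp_sg
  if (sd(delta) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(delta) - 1),
               p.value = 1)
  } else {
    tt <- t.test(rows$rp_ft, rows$rp_sg, paired = TRUE)
  }
  list(
    deltas = tibble(compound = rows$compound %||% seq_along(delta),
                    delta = delta),
    mean = mean(delta), sd = sd(delta),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Frequency-parameter optimisation study
#'
#' Re-runs the full simulate -> reconstruct -> fit pipeline while one plan
#' parameter (`f_max`, `f_min` or `f_step`) moves over a grid, reporting
#' the resolving power of the target peak (the most intense fitted peak,
#' or a named species) with mean and standard deviation over replicate
#' noise realisations, plus the predicted acquisition time of each plan.
#'
#' @param variable One of `"f_max"`, `"f_min"`, `"f_step"`.
#' @param grid Numeric values the variable takes.
#' @param ions Ion-mixture tibble.
#' @param cell A [drift_cell()].
#' @param fixed Named list of the plan parameters held fixed; defaults
#'   `list(f_min = 10, f_step = 5, f_max = 4000, n_avg = 4)` (the grid
#'   value overrides its own entry).
#' @param noise A [noise_model()]; replicate r at grid point i uses seed
#'   `seed + 1000 * i + r`.
#' @param replicates Noise realisations per grid value (default 3,
#'   matching triplicate bench practice).
#' @param window,zero_pad_factor Passed to [reconstruct_spectrum()].
#' @param min_prominence Passed to [fit_peaks()].
#' @param target Optional species name; its drift time (resolved against
#'   `cell`) selects the nearest fitted peak. Default: most intense peak.
#' @param switch_overhead Passed to [plan_duration()].
#' @return Tibble with columns `value`, `mean_rp`, `sd_rp`, `n_steps`,
#'   `duration_s`, `flagged` (TRUE when the target peak was unresolvable
#'   in at least one replicate; such rows are kept, not dropped).
#' @export
run_frequency_study <- function(variable = c("f_max", "f_min", "f_step"),
                                grid, ions, cell = drift_cell(),
                                fixed = list(), noise = noise_model(),
                                replicates = 3,
                                window = "rectangular", zero_pad_factor = 8,
                                min_prominence = 0.1, target = NULL,
                                switch_overhead = 0) {
  variable <- match.arg(variable)
  defaults <- list(f_min = 10, f_step = 5, f_max = 4000, n_avg = 4)
  fixed <- utils::modifyList(defaults, fixed)
  target_td <- NULL
  if (!is.null(target)) {
    res <- resolve_mixture(ions, cell)
    target_td <- res$td[match(target, res$name)]
    if (is.na(target_td)) abort("`target` species not found in the mixture",
                                class = "ftims_error_compare")
  }
  rows <- map(seq_along(grid), function(i) {
    pars <- fixed
    pars[[variable]] <- grid[i]
    plan <- plan_stepped(pars$f_min, pars$f_step, pars$f_max, pars$n_avg,
                         switch_overhead = switch_overhead)
    rp <- vapply(seq_len(replicates), function(r) {
      nm <- noise_model(noise$white_rms, noise$baseline,
                        noise$seed + 1000 * i + r)
      ig <- simulate_interferogram(plan, ions, cell, nm)
      sp <- reconstruct_spectrum(ig, window, zero_pad_factor)
      peaks <- fit_peaks(sp, min_prominence)
      if (nrow(peaks) == 0) return(NA_real_)
      peaks <- resolving_power(peaks)
      if (is.null(target_td)) {
        best <- order(-peaks$height, peaks$td)[1]   # ties: shortest td
      } else {
        best <- which.min(abs(peaks$td - target_td))
      }
      peaks$rp[best]
    }, numeric(1))
    ok <- !is.na(rp)
    tibble(value = grid[i],
           mean_rp = if (any(ok)) mean(rp[ok]) else NA_real_,
           sd_rp = if (sum(ok) > 1) sd(rp[ok]) else 0,
           n_steps = nrow(plan$steps),
           duration_s = plan_duration(plan),
           flagged = any(!ok))
  }) |> list_rbind()
  class(rows) <- c("ftims_study", class(rows))
  attr(rows, "variable") <- variable
  rows
}
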