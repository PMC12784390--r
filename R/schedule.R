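#' Build a stepped-frequency acquisition plan
#'
#' Frequencies run from `f_min` to at most `f_max` in increments of
#' `f_step` (the grid stops at the largest frequency `<= f_max`, keeping the
#' grid uniform for the FFT axis). Averaging follows the constant-time rule:
#' every step dwells for `n_avg / f_min` seconds -- the time needed for
#' `n_avg` periods of the *slowest* frequency -- so each step sums the same
#' wall-clock window of signal regardless of its own frequency. Data
#' windows start `trigger_offset` seconds after the new frequency is
#' established; the offset applies to the data window only, never to the
#' gate waveform phase (the asynchrony under test).
#'
#' @param f_min Lowest frequency, Hz (> 0).
#' @param f_step Frequency increment, Hz (> 0).
#' @param f_max Highest frequency, Hz (>= `f_min`).
#' @param n_avg Number of averages (periods of `f_min`) per step (>= 1).
#' @param trigger_offset Data-window trigger delay after each frequency
#'   change, s. Default 0.5 ms.
#' @param switch_overhead Per-step bookkeeping time beyond the dwell, s.
#'   Default 0 (pure-dwell timing); see [plan_duration()].
#' @return An `ftims_plan` of kind `"stepped"`; `$steps` is a tibble with
#'   columns `f`, `dwell`, `n_pulses`, `trigger_offset`.
#' @examples
#' plan <- plan_stepped(4, 5, 4000, n_avg = 4)   # 1 s dwell at every step
#' head(plan$steps)
#' @export
plan_stepped <- function(f_min, f_step, f_max, n_avg,
                         trigger_offset = 0.0005, switch_overhead = 0) {
  if (f_min <= 0 || f_max <= 0) {
    abort("frequencies must be > 0", class = "ftims_error_plan")
  }
  if (f_min > f_max) {
    abort("`f_min` must not exceed `f_max`", class = "ftims_error_plan")
  }
  if (f_step <= 0) abort("`f_step` must be > 0", class = "ftims_error_plan")
  if (n_avg < 1) abort("`n_avg` must be >= 1", class = "ftims_error_plan")
  n_steps <- floor((f_max - f_min) / f_step + 1e-9) + 1
  f <- f_min + f_step * (seq_len(n_steps) - 1)
  dwell <- n_avg / f_min
  steps <- tibble(
    f = f,
    dwell = dwell,
    n_pulses = floor(dwell * f + 1e-9),
    trigger_offset = trigger_offset
  )
  structure(
    list(kind = "stepped", f_min = f_min, f_step = f_step, f_max = f_max,
         n_avg = n_avg, trigger_offset = trigger_offset,
         switch_overhead = switch_overhead, steps = steps),
    class = "ftims_plan")
}

#' Build a swept (linear-chirp) acquisition plan
#'
#' The gate frequency ramps linearly from `f_min` to `f_max` over
#' `sweep_duration` seconds: instantaneous frequency
#' `f(t) = f_min + (f_max - f_min) * t / sweep_duration`.
#'
#' @param f_min Start frequency, Hz (> 0).
#' @param f_max End frequency, Hz (> `f_min`).
#' @param sweep_duration Sweep length, s (> 0).
#' @param n_avg Number of repeated sweeps averaged.
#' @return An `ftims_plan` of kind `"swept"` carrying the chirp rate
#'   (`$rate`, Hz/s).
#' @examples
#' plan_swept(4, 8000, 8, n_avg = 100)$rate   # 999.5 Hz/s
#' @export
plan_swept <- function(f_min, f_max, sweep_duration, n_avg = 1) {
  if (f_min <= 0 || f_max <= f_min) {
    abort("need 0 < f_min < f_max", class = "ftims_error_plan")
  }
  if (sweep_duration <= 0) {
    abort("`sweep_duration` must be > 0", class = "ftims_error_plan")
  }
  structure(
    list(kind = "swept", f_min = f_min, f_max = f_max,
         sweep_duration = sweep_duration, n_avg = n_avg,
         rate = (f_max - f_min) / sweep_duration),
    class = "ftims_plan")
}

#' Build a pulsed single-gate acquisition plan
#'
#' Conventional signal-averaged drift-tube operation: a short gate pulse
#' opens once per scan and the arrival-time trace is averaged over
#' `n_scans` repeats. Defaults follow common bench practice for a ~50 ms
#' drift window (50 ms scan, 0.2 ms pulse, 275 averages), giving the
#' 0.1--0.5% duty cycle typical of pulsed operation.
#'
#' @param scan_time Scan length, ms.
#' @param pulse_width Gate pulse width, ms (< `scan_time`).
#' @param n_scans Number of averaged scans (>= 1).
#' @return An `ftims_plan` of kind `"single_gate"`.
#' @export
plan_single_gate <- function(scan_time = 50, pulse_width = 0.2, n_scans = 275) {
  if (pulse_width >= scan_time) {
    abort("`pulse_width` must be smaller than `scan_time`",
          class = "ftims_error_plan")
  }
  if (scan_time <= 0 || pulse_width <= 0 || n_scans < 1) {
    abort("scan_time, pulse_width > 0 and n_scans >= 1 required",
          class = "ftims_error_plan")
  }
  structure(
    list(kind = "single_gate", scan_time = scan_time,
         pulse_width = pulse_width, n_scans = n_scans,
         duty = pulse_width / scan_time),
    class = "ftims_plan")
}

#' @export
print.ftims_plan <- function(x, ...) {
  switch(x$kind,
    stepped = cat(sprintf(
      "<stepped plan: %g -> %g Hz by %g Hz (%d steps), dwell %g s, trigger offset %g s>\n",
      x$f_min, max(x$steps$f), x$f_step, nrow(x$steps), x$steps$dwell[1],
      x$trigger_offset)),
    swept = cat(sprintf(
      "<swept plan: %g -> %g Hz over %g s (%g Hz/s), %d averages>\n",
      x$f_min, x$f_max, x$sweep_duration, x$rate, x$n_avg)),
    single_gate = cat(sprintf(
      "<single-gate plan: %g ms scan, %g ms pulse, %d averages (duty %.2f%%)>\n",
      x$scan_time, x$pulse_width, x$n_scans, 100 * x$duty))
  )
  invisible(x)
}

#' Total acquisition time of a plan
#'
#' Stepped plans: `sum(dwell + switch_overhead)` over steps. Swept plans:
#' `n_avg * sweep_duration`. Single-gate plans: `n_scans * scan_time`.
#' Real controllers add per-step bookkeeping time that the dwell rule alone
#' does not capture; pass it as `switch_overhead` to see wall-clock
#' estimates.
#'
#' @param plan An `ftims_plan`.
#' @param switch_overhead Per-step overhead, s; defaults to the value stored
#'   in the plan (0 unless set).
#' @return Duration in seconds.
#' @examples
#' plan_duration(plan_stepped(2, 2, 4000, 2))   # 2000 steps x 1 s
#' @export
plan_duration <- function(plan, switch_overhead = NULL) {
  check_plan(plan)
  switch(plan$kind,
    stepped = {
      oh <- switch_overhead %||% plan$switch_overhead %||% 0
      sum(plan$steps$dwell + oh)
    },
    swept = plan$n_avg * plan$sweep_duration,
    single_gate = plan$n_scans * plan$scan_time / 1000
  )
}

check_plan <- function(plan, kind = NULL) {
  if (!inherits(plan, "ftims_plan")) {
    abort("`plan` must be an ftims_plan", class = "ftims_error_plan")
  }
  if (!is.null(kind) && plan$kind != kind) {
    abort(sprintf("this operation needs a %s plan (got %s)", kind, plan$kind),
          class = "ftims_error_plan")
  }
  invisible(plan)
}

#' Sampled gate-drive waveform for one frequency step
#'
#' Both gates share one square-wave drive (a single controller output split
#' to the two gate pulsers), so a single open/closed series describes them
#' both.
#'
#' @param f Gate frequency, Hz, or a one-row step tibble with columns `f`
#'   and `dwell` (e.g. one row of `plan$steps`).
#' @param duration Length of the series, s. Defaults to the step's dwell
#'   when `f` is a step row.
#' @param sample_rate Samples per second; must be at least `10 * f`.
#' @param duty Duty cycle, fraction in (0, 0.5].
#' @return Tibble with columns `time_s` and `open` (0/1).
#' @export
gate_waveform <- function(f, duration = NULL, sample_rate, duty = 0.5) {
  if (is.data.frame(f)) {
    duration <- duration %||% f$dwell[1]
    f <- f$f[1]
  }
  if (is.null(duration)) abort("`duration` is required",
                               class = "ftims_error_plan")
  if (sample_rate < 10 * f) {
    abort("`sample_rate` must be >= 10 * f to avoid aliasing the gate drive",
          class = "ftims_error_sampling")
  }
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  tibble(time_s = t, open = as.integer(((t * f) %% 1) < duty))
}
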