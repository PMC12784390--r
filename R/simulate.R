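new_interferogram <- function(frequency_hz, signal, meta) {
  out <- tibble(frequency_hz = frequency_hz, signal = signal)
  class(out) <- c("ftims_interferogram", class(out))
  attr(out, "f_step") <- meta$f_step
  attr(out, "meta") <- meta
  out
}

#' Simulate a stepped-frequency interferogram (steady-state model)
#'
#' For each frequency step the dual-gate cell produces a steady DC level:
#' the sum over species of `abundance * E[gate_correlation(f, t)]`, the
#' expectation taken over each species' Gaussian arrival-time distribution
#' (mean `td`, sd `sigma`), plus the baseline. White noise is added per
#' step with standard deviation `white_rms / sqrt(dwell * f)` -- the
#' averaging window at step frequency `f` spans `dwell * f` gate periods.
#' Noise draws use per-step substreams of the model seed, so results are
#' reproducible and independent of plan length.
#'
#' @param plan A stepped [plan_stepped()] plan.
#' @param ions Ion-mixture tibble ([ion_mixture()]); may be empty (pure
#'   baseline + noise).
#' @param cell A [drift_cell()] used to resolve drift times.
#' @param noise A [noise_model()].
#' @param duty Gate duty cycle.
#' @return An interferogram: tibble with columns `frequency_hz`, `signal`,
#'   class `ftims_interferogram`, uniform frequency grid.
#' @examples
#' ig <- simulate_interferogram(plan_stepped(10, 5, 4000, 4),
#'                              fixture_mixture("rip")$ions)
#' @export
simulate_interferogram <- function(plan, ions = ion_mixture(),
                                   cell = drift_cell(),
                                   noise = noise_model(), duty = 0.5) {
  check_plan(plan, "stepped")
  f <- plan$steps$f
  sig <- rep(noise$baseline, length(f))
  if (nrow(ions) > 0) {
    ions <- resolve_mixture(ions, cell)
    for (i in seq_len(nrow(ions))) {
      sig <- sig + ions$abundance[i] *
        gate_correlation_smeared(f, ions$td[i], ions$sigma[i], duty)
    }
  }
  if (noise$white_rms > 0) {
    sd_k <- noise$white_rms / sqrt(plan$steps$dwell * f)
    draws <- vapply(seq_along(f), function(k) {
      with_substream(noise$seed, k, rnorm(1L, 0, sd_k[k]))
    }, numeric(1))
    sig <- sig + draws
  }
  new_interferogram(f, sig, meta = list(
    kind = "stepped", f_min = plan$f_min, f_step = plan$f_step,
    f_max = plan$f_max, n_avg = plan$n_avg, duty = duty,
    seed = noise$seed, baseline = noise$baseline,
    white_rms = noise$white_rms))
}

# analytic square gate drive, arbitrary (possibly negative) times
square_open <- function(f, t, duty = 0.5) {
  as.numeric(((t * f) %% 1) < duty)
}

#' Simulate the sampled amplifier output over one frequency step
#'
#' Brute-force time-domain model of a single dwell: an explicit square
#' gate-drive train, ion packets delayed by their (Gaussian) drift-time
#' distribution, chopping at the second gate, and a single-pole low-pass
#' amplifier with time constant `rise_time / 2.2`. The filter starts from
#' the record's DC level, representing continuation from the established
#' steady state of the running experiment. Use [record_mean()] to average
#' the record over a data window; with a long rise time that mean is
#' insensitive to where the window starts, which is what licenses
#' asynchronous software triggering.
#'
#' @param step One row of a stepped plan's `$steps` (or a list/tibble with
#'   `f`, `dwell`, `trigger_offset`).
#' @param ions Ion-mixture tibble.
#' @param cell A [drift_cell()].
#' @param amp An [amplifier()].
#' @param noise A [noise_model()]; white noise is added to the raw detector
#'   samples before filtering.
#' @param sample_rate Samples per second; must be >= 20 times the step
#'   frequency.
#' @param duty Gate duty cycle.
#' @param step_index Integer used to derive the noise substream.
#' @return Tibble with columns `time_s`, `signal`; attributes `f`, `dwell`,
#'   `trigger_offset`.
#' @export
simulate_time_domain <- function(step, ions, cell = drift_cell(),
                                 amp = amplifier(), noise = noise_model(),
                                 sample_rate, duty = 0.5, step_index = 0L) {
  f <- step$f[1]
  dwell <- step$dwell[1]
  trigger_offset <- if (!is.null(step$trigger_offset)) step$trigger_offset[1] else 0
  if (sample_rate < 20 * f) {
    abort("`sample_rate` must be >= 20 * f for the time-domain record",
          class = "ftims_error_sampling")
  }
  n <- round(dwell * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  gate <- square_open(f, t, duty)
  flux <- rep(0, n)
  if (nrow(ions) > 0) {
    ions <- resolve_mixture(ions, cell)
    for (i in seq_len(nrow(ions))) {
      td_s <- ions$td[i] * 1e-3
      sg_s <- ions$sigma[i] * 1e-3
      if (ions$abundance[i] == 0) next
      if (sg_s <= 0) {
        flux <- flux + ions$abundance[i] * square_open(f, t - td_s, duty)
      } else {
        z <- seq(-6, 6, length.out = 81)
        w <- dnorm(z); w <- w / sum(w)
        sm <- rep(0, n)
        for (j in seq_along(z)) {
          sm <- sm + w[j] * square_open(f, t - td_s - sg_s * z[j], duty)
        }
        flux <- flux + ions$abundance[i] * sm
      }
    }
  }
  raw <- noise$baseline + flux * gate
  if (noise$white_rms > 0) {
    raw <- raw + with_substream(noise$seed, step_index,
                                rnorm(n, 0, noise$white_rms))
  }
  out_sig <- lowpass(raw, sample_rate, amp$rise_time)
  out <- tibble(time_s = t, signal = out_sig)
  attr(out, "f") <- f
  attr(out, "dwell") <- dwell
  attr(out, "trigger_offset") <- trigger_offset
  out
}

# single-pole RC low-pass; rise_time is the 10-90% time in ms, tau = rt/2.2.
# Initialised at the record's DC level (continuation from steady state).
lowpass <- function(x, sample_rate, rise_time_ms) {
  if (rise_time_ms <= 0) return(x)
  tau <- rise_time_ms / 2.2 / 1000
  dt <- 1 / sample_rate
  alpha <- dt / (tau + dt)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = mean(x)))
}

#' Windowed mean of a time-domain record
#'
#' Averages the record from `from` seconds to its end; with
#' `whole_periods = TRUE` the window is truncated to an integer number of
#' gate periods (exact averaging of the unfiltered ripple).
#'
#' @param record Output of [simulate_time_domain()].
#' @param from Window start, s; defaults to the record's trigger offset.
#' @param whole_periods Truncate the window to whole gate periods?
#' @return The mean signal over the window.
#' @export
record_mean <- function(record, from = NULL, whole_periods = FALSE) {
  from <- from %||% attr(record, "trigger_offset") %||% 0
  f <- attr(record, "f")
  keep <- record$time_s >= from - 1e-12
  t <- record$time_s[keep]
  x <- record$signal[keep]
  if (whole_periods) {
    span <- floor((t[length(t)] - t[1] + 1e-12) * f) / f
    inwin <- t <= t[1] + span - 1e-12
    x <- x[inwin]
  }
  mean(x)
}

#' Simulate an averaged single-gate arrival-time trace
#'
#' Each species contributes a Gaussian arrival peak centred at its drift
#' time with standard deviation `sqrt(sigma^2 + (pulse_width / 2.355)^2)`
#' (intrinsic width plus injected-pulse width), with amplitude proportional
#' to `abundance * pulse_width` (charge admitted per pulse). The trace is
#' passed through the amplifier low-pass, and white noise is attenuated by
#' `1 / sqrt(n_scans)` by the signal averaging.
#'
#' @param plan A [plan_single_gate()] plan.
#' @param ions Ion-mixture tibble.
#' @param cell A [drift_cell()].
#' @param amp An [amplifier()]; single-gate work uses a fast rise time
#'   (default here 0.1 ms).
#' @param noise A [noise_model()].
#' @param sample_rate Samples per second on the arrival axis (default
#'   20 kHz, i.e. 0.05 ms spacing).
#' @return Tibble with columns `time_ms`, `signal`, class
#'   `ftims_arrival_trace`.
#' @export
simulate_single_gate <- function(plan, ions, cell = drift_cell(),
                                 amp = amplifier(rise_time = 0.1),
                                 noise = noise_model(), sample_rate = 20000) {
  check_plan(plan, "single_gate")
  dt_ms <- 1000 / sample_rate
  t_ms <- seq(0, plan$scan_time, by = dt_ms)
  sig <- rep(noise$baseline, length(t_ms))
  if (nrow(ions) > 0) {
    ions <- resolve_mixture(ions, cell)
    width <- sqrt(ions$sigma^2 + (plan$pulse_width / 2.355)^2)
    for (i in seq_len(nrow(ions))) {
      sig <- sig + ions$abundance[i] * plan$pulse_width *
        dnorm(t_ms, ions$td[i], width[i])
    }
  }
  if (noise$white_rms > 0) {
    sig <- sig + with_substream(noise$seed, 0L,
      rnorm(length(t_ms), 0, noise$white_rms / sqrt(plan$n_scans)))
  }
  sig <- lowpass(sig, sample_rate, amp$rise_time)
  out <- tibble(time_ms = t_ms, signal = sig)
  class(out) <- c("ftims_arrival_trace", class(out))
  attr(out, "meta") <- list(kind = "single_gate", scan_time = plan$scan_time,
                            pulse_width = plan$pulse_width,
                            n_scans = plan$n_scans, seed = noise$seed)
  out
}

#' Simulate a swept (chirp) frequency record
#'
#' The instantaneous gate frequency ramps linearly with time; each sample
#' carries the steady-state dual-gate transmission evaluated at the
#' instantaneous frequency, plus baseline and white noise attenuated by
#' `1 / sqrt(n_avg)` sweep averaging.
#'
#' @param plan A [plan_swept()] plan.
#' @param ions Ion-mixture tibble.
#' @param cell A [drift_cell()].
#' @param noise A [noise_model()].
#' @param sample_rate Samples per second along the sweep.
#' @param duty Gate duty cycle.
#' @return Tibble with columns `time_s`, `frequency_hz`, `signal`.
#' @export
simulate_swept <- function(plan, ions, cell = drift_cell(),
                           noise = noise_model(), sample_rate = 1000,
                           duty = 0.5) {
  check_plan(plan, "swept")
  t <- seq(0, plan$sweep_duration - 1 / sample_rate, by = 1 / sample_rate)
  f_inst <- plan$f_min + plan$rate * t
  sig <- rep(noise$baseline, length(t))
  if (nrow(ions) > 0) {
    ions <- resolve_mixture(ions, cell)
    for (i in seq_len(nrow(ions))) {
      sig <- sig + ions$abundance[i] *
        gate_correlation_smeared(f_inst, ions$td[i], ions$sigma[i], duty)
    }
  }
  if (noise$white_rms > 0) {
    sig <- sig + with_substream(noise$seed, 0L,
      rnorm(length(t), 0, noise$white_rms / sqrt(plan$n_avg)))
  }
  out <- tibble(time_s = t, frequency_hz = f_inst, signal = sig)
  class(out) <- c("ftims_swept_record", class(out))
  attr(out, "meta") <- list(kind = "swept", f_min = plan$f_min,
                            f_max = plan$f_max, rate = plan$rate,
                            sweep_duration = plan$sweep_duration,
                            n_avg = plan$n_avg, seed = noise$seed)
  out
}

#' Rebin a swept record onto a uniform frequency grid
#'
#' A linear chirp visits frequency uniformly in time, so samples can be
#' averaged into `f_step`-wide bins to produce an interferogram directly
#' comparable with a stepped acquisition.
#'
#' @param record Output of [simulate_swept()].
#' @param f_step Width of the frequency bins, Hz.
#' @return An `ftims_interferogram`.
#' @export
swept_to_interferogram <- function(record, f_step) {
  meta <- attr(record, "meta")
  if (is.null(meta) || !identical(meta$kind, "swept")) {
    abort("`record` must come from simulate_swept()", class = "ftims_error_plan")
  }
  bin <- round((record$frequency_hz - meta$f_min) / f_step)
  agg <- tibble(bin = bin, signal = record$signal) |>
    group_by(bin) |>
    summarise(signal = mean(.data$signal), n = dplyr::n(), .groups = "drop") |>
    filter(.data$n > 0)
  f <- meta$f_min + agg$bin * f_step
  new_interferogram(f, agg$signal, meta = list(
    kind = "swept_rebinned", f_min = min(f), f_step = f_step, f_max = max(f),
    n_avg = meta$n_avg, duty = 0.5, seed = meta$seed))
}
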