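#' Drift time from reduced mobility
#'
#' In geometry mode the standard drift-tube relation is used:
#' `td = L / (K * E)` with `K = K0 * (T / 273.15) * (760 / P)` (mobility at
#' the cell's temperature and pressure, referenced to the 273.15 K / 760 Torr
#' standard state). In calibration mode `td = C / K0`.
#'
#' @param K0 Reduced mobility, cm^2 V^-1 s^-1 (vectorised, all > 0).
#' @param cell A [drift_cell()].
#' @return Drift time(s) in ms.
#' @examples
#' drift_time(1.23, drift_cell(C = 43.12))   # 35.06 ms
#' @export
drift_time <- function(K0, cell) {
  check_cell(cell)
  if (any(is.na(K0))) {
    abort("species without `K0` cannot be placed on the drift-time axis; resolve it first",
          class = "ftims_error_species")
  }
  if (any(K0 <= 0)) abort("`K0` must be > 0", class = "ftims_error_species")
  if (cell$mode == "calibration") {
    cell$C / K0
  } else {
    K <- K0 * (cell$T / 273.15) * (760 / cell$P)
    1000 * cell$L / (K * cell$E)   # s -> ms
  }
}

#' Reduced mobility from drift time
#'
#' Inverse of [drift_time()]: `K0 = (L / (td * E)) * (273.15 / T) * (P / 760)`
#' in geometry mode, `K0 = C / td` in calibration mode.
#'
#' @param td Drift time, ms (vectorised, all > 0).
#' @inheritParams drift_time
#' @return Reduced mobility value(s), cm^2 V^-1 s^-1.
#' @examples
#' reduced_mobility(35.06, drift_cell(C = 43.12))   # 1.23
#' @export
reduced_mobility <- function(td, cell) {
  check_cell(cell)
  if (any(is.na(td) | td <= 0)) {
    abort("`td` must be > 0 (ms)", class = "ftims_error_species")
  }
  if (cell$mode == "calibration") {
    cell$C / td
  } else {
    K <- 1000 * cell$L / (td * cell$E)         # mobility at cell conditions
    K * (273.15 / cell$T) * (cell$P / 760)
  }
}

check_cell <- function(cell) {
  if (!inherits(cell, "ftims_cell")) {
    abort("`cell` must be a drift_cell()", class = "ftims_error_cell")
  }
  invisible(cell)
}

#' Complete an ion-mixture table against a drift cell
#'
#' Fills whichever of `K0` / `td` is missing for each species, so that every
#' row carries both a mobility and a drift time.
#'
#' @param ions Ion-mixture tibble (see [ion_mixture()]).
#' @inheritParams drift_time
#' @return The mixture tibble with `K0` and `td` both populated.
#' @export
resolve_mixture <- function(ions, cell = drift_cell()) {
  validate_mixture(ions)
  check_cell(cell)
  need_td <- is.na(ions$td)
  if (any(need_td)) ions$td[need_td] <- drift_time(ions$K0[need_td], cell)
  need_k0 <- is.na(ions$K0)
  if (any(need_k0)) ions$K0[need_k0] <- reduced_mobility(ions$td[need_k0], cell)
  ions
}

#' Gate frequency matched to a drift time
#'
#' The dual-gate correlation signal is maximal when the gate period equals
#' the drift time, i.e. at `f = 1000 / td` for `td` in ms (a 20 ms drift
#' time is matched by 50 Hz).
#'
#' @param td Drift time, ms.
#' @return Frequency in Hz.
#' @export
matched_frequency <- function(td) {
  if (any(td <= 0)) abort("`td` must be > 0 (ms)", class = "ftims_error_species")
  1000 / td
}

#' Dual-gate transmission at one modulation frequency
#'
#' Both ion gates are driven by the same square wave of frequency `f` and
#' duty cycle `duty`. An ion swarm with drift time `td` reaches the second
#' gate delayed by `td`, so the time-averaged transmitted fraction is the
#' circular overlap of two duty-`duty` square waves offset by the phase
#' `phi = frac(f * td)` -- a triangular function of `phi`. For the FT
#' experiment's 50% duty this is `0.5 * (1 - 2 * min(phi, 1 - phi))`:
#' maximal (`0.5`) when gate period and drift time match, zero in
#' anti-phase.
#'
#' @param f Gate modulation frequency, Hz (> 0). Vectorised.
#' @param td Drift time, ms (> 0). Vectorised (recycled against `f`).
#' @param duty Gate duty cycle, fraction in (0, 0.5].
#' @return Transmission fraction(s) in `[0, duty]`.
#' @examples
#' gate_correlation(50, 20)    # matched: 0.5
#' gate_correlation(75, 20)    # anti-phase (phi = 0.5): 0
#' @export
gate_correlation <- function(f, td, duty = 0.5) {
  if (any(f <= 0)) abort("`f` must be > 0 (Hz)", class = "ftims_error_gate")
  if (any(td <= 0)) abort("`td` must be > 0 (ms)", class = "ftims_error_gate")
  if (duty <= 0 || duty > 0.5) {
    abort("`duty` must be in (0, 0.5]", class = "ftims_error_gate")
  }
  phi <- (f * td * 1e-3) %% 1
  # circular overlap of two width-`duty` pulses offset by phi (period 1)
  pmax(0, duty - phi) + pmax(0, duty - (1 - phi))
}

# Expected gate transmission when the arrival time is Gaussian:
# E[g(f, t)], t ~ N(td, sigma), evaluated by quadrature of the exact
# piecewise-linear overlap over +/- 6 sigma. sigma in ms.
gate_correlation_smeared <- function(f, td, sigma = 0, duty = 0.5) {
  if (sigma <= 0) return(gate_correlation(f, td, duty))
  z <- seq(-6, 6, length.out = 241)
  w <- dnorm(z)
  w <- w / sum(w)
  out <- numeric(length(f))
  for (j in seq_along(z)) {
    out <- out + w[j] * gate_correlation(f, td + sigma * z[j], duty)
  }
  out
}
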