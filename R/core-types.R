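#' Declare a single ion species
#'
#' An ion species is described by its reduced mobility `K0`
#' (cm^2 V^-1 s^-1) and/or its drift time `td` (ms) in a given drift cell,
#' together with a relative abundance and an intrinsic arrival-time spread.
#' One of `K0` and `td` may be omitted; the other is derivable once a
#' [drift_cell()] is supplied (see [resolve_mixture()]).
#'
#' @param name Character label for the species.
#' @param K0 Reduced mobility, cm^2 V^-1 s^-1 (> 0), or `NA`.
#' @param td Drift time, ms (> 0), or `NA`.
#' @param abundance Relative abundance (>= 0). Dimensionless; sets the
#'   species' contribution to the detector signal.
#' @param sigma Intrinsic arrival-time standard deviation, ms (>= 0).
#'   Captures diffusional/gate broadening beyond the transform limit.
#' @return A one-row tibble with columns `name`, `K0`, `td`, `abundance`,
#'   `sigma`. Bind rows of these (or call [ion_mixture()]) to build a mixture.
#' @examples
#' ion_species("T4A", K0 = 1.23, abundance = 1, sigma = 0.18)
#' @export
ion_species <- function(name, K0 = NA_real_, td = NA_real_,
                        abundance = 1, sigma = 0) {
  if (is.na(K0) && is.na(td)) {
    abort("an ion species needs at least one of `K0` or `td`",
          class = "ftims_error_species")
  }
  if (!is.na(K0) && K0 <= 0) {
    abort("`K0` must be > 0", class = "ftims_error_species")
  }
  if (!is.na(td) && td <= 0) {
    abort("`td` must be > 0 (ms)", class = "ftims_error_species")
  }
  if (abundance < 0 || sigma < 0) {
    abort("`abundance` and `sigma` must be >= 0", class = "ftims_error_species")
  }
  tibble(name = as.character(name), K0 = as.numeric(K0), td = as.numeric(td),
         abundance = as.numeric(abundance), sigma = as.numeric(sigma))
}

#' Build an ion mixture table
#'
#' @param ... One-row tibbles from [ion_species()], or data frames with the
#'   same columns.
#' @return A tibble with one row per species.
#' @examples
#' ion_mixture(
#'   ion_species("RIP", td = 20, sigma = 0.15),
#'   ion_species("analyte", td = 30, sigma = 0.15, abundance = 0.6)
#' )
#' @export
ion_mixture <- function(...) {
  out <- bind_rows(...)
  if (nrow(out) == 0) {
    return(tibble(name = character(), K0 = numeric(), td = numeric(),
                  abundance = numeric(), sigma = numeric()))
  }
  validate_mixture(out)
  out
}

validate_mixture <- function(ions) {
  need <- c("name", "K0", "td", "abundance", "sigma")
  missing_cols <- setdiff(need, names(ions))
  if (length(missing_cols)) {
    abort(paste0("ion mixture is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ftims_error_species")
  }
  if (any(is.na(ions$K0) & is.na(ions$td))) {
    abort("every species needs at least one of `K0` or `td`",
          class = "ftims_error_species")
  }
  invisible(ions)
}

#' Describe a drift cell
#'
#' Two parameterisations are supported. In *geometry* mode the cell is given
#' by its drift length `L` (cm), field `E` (V cm^-1), temperature `T` (K) and
#' pressure `P` (Torr), and drift times follow from the standard drift-tube
#' relation. In *calibration* mode the cell is summarised by a single
#' constant `C = td * K0` (ms cm^2 V^-1 s^-1): given either of `td`/`K0` the
#' other follows, without knowing the geometry. The default cell is
#' calibration mode with `C` taken as the mean of `td * K0` over the
#' single-gate tetraalkylammonium rows of the bundled benchmark table
#' ([reference_compounds()]), i.e. a cell calibrated against mobility
#' standards.
#'
#' @param C Calibration constant, ms cm^2 V^-1 s^-1 (> 0). Mutually
#'   exclusive with `L`/`E`.
#' @param L Drift length, cm (> 0).
#' @param E Drift field, V cm^-1 (> 0).
#' @param T Temperature, K (> 0). Used in geometry mode only.
#' @param P Pressure, Torr (> 0). Used in geometry mode only.
#' @return An object of class `ftims_cell`.
#' @examples
#' drift_cell()                      # standards-calibrated cell
#' drift_cell(L = 16.4, E = 350)     # explicit geometry at STP
#' @export
drift_cell <- function(C = NULL, L = NULL, E = NULL, T = 273.15, P = 760) {
  if (!is.null(C) && (!is.null(L) || !is.null(E))) {
    abort("give either `C` (calibration) or `L` and `E` (geometry), not both",
          class = "ftims_error_cell")
  }
  if (is.null(C) && is.null(L) && is.null(E)) {
    C <- default_calibration_constant()
  }
  if (!is.null(C)) {
    if (C <= 0) abort("`C` must be > 0", class = "ftims_error_cell")
    cell <- list(mode = "calibration", C = C, T = T, P = P)
  } else {
    if (is.null(L) || is.null(E)) {
      abort("geometry mode needs both `L` and `E`", class = "ftims_error_cell")
    }
    if (any(c(L, E, T, P) <= 0)) {
      abort("`L`, `E`, `T`, `P` must all be > 0", class = "ftims_error_cell")
    }
    cell <- list(mode = "geometry", L = L, E = E, T = T, P = P)
  }
  structure(cell, class = "ftims_cell")
}

#' @export
print.ftims_cell <- function(x, ...) {
  if (x$mode == "calibration") {
    cat(sprintf("<drift cell: calibration mode, C = %.4f ms cm^2/(V s)>\n", x$C))
  } else {
    cat(sprintf(
      "<drift cell: geometry mode, L = %g cm, E = %g V/cm, T = %g K, P = %g Torr>\n",
      x$L, x$E, x$T, x$P))
  }
  invisible(x)
}

# mean td*K0 over the single-gate tetraalkylammonium standards
default_calibration_constant <- function() {
  ref <- reference_compounds()
  txa <- ref[ref$compound %in% c("T3A", "T4A", "T5A", "T6A"), ]
  mean(txa$td_sg * txa$k0_sg)
}

#' Describe the current amplifier
#'
#' The Faraday-plate current amplifier is modelled as a single-pole RC
#' low-pass with time constant `rise_time / 2.2` (the 10--90% rise-time
#' convention). A long rise time (default 100 ms, typical for FT-mode
#' drift-tube work) smooths the per-period gate ripple into a steady DC
#' level, which is what makes asynchronous, software-timed data windows
#' valid.
#'
#' @param gain Transimpedance gain, V A^-1 (> 0). Metadata only: simulated
#'   signals are kept in normalised ion-transmission units.
#' @param rise_time 10--90% rise time, ms (>= 0). `0` means pass-through.
#' @return An object of class `ftims_amplifier`.
#' @export
amplifier <- function(gain = 1e9, rise_time = 100) {
  if (gain <= 0) abort("`gain` must be > 0", class = "ftims_error_amplifier")
  if (rise_time < 0) abort("`rise_time` must be >= 0",
                           class = "ftims_error_amplifier")
  structure(list(gain = gain, rise_time = rise_time),
            class = "ftims_amplifier")
}

#' @export
print.ftims_amplifier <- function(x, ...) {
  cat(sprintf("<amplifier: gain %.3g V/A, rise time %g ms>\n",
              x$gain, x$rise_time))
  invisible(x)
}

#' Describe the additive noise model
#'
#' White Gaussian noise plus a constant baseline offset, with a seed so that
#' identical parameters give a bit-identical noise stream. Per-step noise
#' substreams are derived deterministically from `seed` and the step index,
#' so the draw at a given frequency step does not depend on how many other
#' steps the plan contains.
#'
#' @param white_rms Standard deviation of the raw white noise, arbitrary
#'   signal units (>= 0).
#' @param baseline Constant signal offset.
#' @param seed Integer RNG seed.
#' @return An object of class `ftims_noise`.
#' @export
noise_model <- function(white_rms = 0, baseline = 0, seed = 1L) {
  if (white_rms < 0) abort("`white_rms` must be >= 0",
                           class = "ftims_error_noise")
  structure(list(white_rms = white_rms, baseline = baseline,
                 seed = as.integer(seed)),
            class = "ftims_noise")
}

#' @export
print.ftims_noise <- function(x, ...) {
  cat(sprintf("<noise: white rms %g, baseline %g, seed %d>\n",
              x$white_rms, x$baseline, x$seed))
  invisible(x)
}

# deterministic substream: run `expr` under seed derived from (seed, index),
# leaving the caller's RNG state untouched
with_substream <- function(seed, index, expr) {
  withr::with_seed(as.integer((as.double(seed) + 104729 * index) %% 2147483647L),
                   expr)
}
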