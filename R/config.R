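#' Read and validate a run configuration
#'
#' One YAML document declares an entire run: the ion mixture, drift cell,
#' amplifier, noise model, acquisition plan, and reconstruction/analysis
#' settings, plus a global `seed` and schema `version`. Unknown keys at
#' the top level or inside a section are rejected, so typos fail loudly
#' rather than silently falling back to defaults.
#'
#' Sections and keys (all optional unless noted):
#' \describe{
#'   \item{ions}{list of `{name, K0 or td, abundance, sigma}` entries, or
#'     `fixture: <name>` to use [fixture_mixture()].}
#'   \item{cell}{`{C}` or `{L, E, T, P}`.}
#'   \item{amplifier}{`{gain, rise_time}`.}
#'   \item{noise}{`{white_rms, baseline}` (the global seed is used).}
#'   \item{plan}{`kind: stepped|swept|single_gate` plus that kind's
#'     parameters (required for simulation).}
#'   \item{reconstruct}{`{window, zero_pad_factor}`.}
#'   \item{analyze}{`{min_prominence, noise_region}`.}
#' }
#'
#' @param path YAML file path.
#' @return A list of constructed objects: `ions`, `cell`, `amplifier`,
#'   `noise`, `plan`, `reconstruct`, `analyze`, `seed`, `version`, with
#'   class `ftims_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("ions", "cell", "amplifier", "noise", "plan", "reconstruct",
             "analyze", "seed", "version")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")),
          class = "ftims_error_config")
  }
  seed <- as.integer(raw$seed %||% 1L)

  ions <- if (is.null(raw$ions)) {
    ion_mixture()
  } else if (!is.null(raw$ions$fixture)) {
    check_keys(raw$ions, "ions", "fixture")
    fixture_mixture(raw$ions$fixture)$ions
  } else {
    bind_rows(map(raw$ions, function(sp) {
      check_keys(sp, "ions[]", c("name", "K0", "td", "abundance", "sigma"))
      ion_species(sp$name %||% "ion", K0 = sp$K0 %||% NA_real_,
                  td = sp$td %||% NA_real_,
                  abundance = sp$abundance %||% 1, sigma = sp$sigma %||% 0)
    }))
  }

  cell <- if (is.null(raw$cell)) {
    drift_cell()
  } else {
    check_keys(raw$cell, "cell", c("C", "L", "E", "T", "P"))
    drift_cell(C = raw$cell$C, L = raw$cell$L, E = raw$cell$E,
               T = raw$cell$T %||% 273.15, P = raw$cell$P %||% 760)
  }

  amp <- if (is.null(raw$amplifier)) {
    amplifier()
  } else {
    check_keys(raw$amplifier, "amplifier", c("gain", "rise_time"))
    amplifier(gain = raw$amplifier$gain %||% 1e9,
              rise_time = raw$amplifier$rise_time %||% 100)
  }

  noise <- if (is.null(raw$noise)) {
    noise_model(seed = seed)
  } else {
    check_keys(raw$noise, "noise", c("white_rms", "baseline"))
    noise_model(white_rms = raw$noise$white_rms %||% 0,
                baseline = raw$noise$baseline %||% 0, seed = seed)
  }

  plan <- if (is.null(raw$plan)) NULL else {
    p <- raw$plan
    kind <- p$kind %||% "stepped"
    switch(kind,
      stepped = {
        check_keys(p, "plan", c("kind", "f_min", "f_step", "f_max", "n_avg",
                                "trigger_offset", "switch_overhead"))
        plan_stepped(p$f_min, p$f_step, p$f_max, p$n_avg %||% 1,
                     trigger_offset = p$trigger_offset %||% 0.0005,
                     switch_overhead = p$switch_overhead %||% 0)
      },
      swept = {
        check_keys(p, "plan", c("kind", "f_min", "f_max", "sweep_duration",
                                "n_avg"))
        plan_swept(p$f_min, p$f_max, p$sweep_duration, p$n_avg %||% 1)
      },
      single_gate = {
        check_keys(p, "plan", c("kind", "scan_time", "pulse_width", "n_scans"))
        plan_single_gate(p$scan_time %||% 50, p$pulse_width %||% 0.2,
                         p$n_scans %||% 275)
      },
      abort(paste0("unknown plan kind: ", kind), class = "ftims_error_config")
    )
  }

  rec <- raw$reconstruct %||% list()
  check_keys(rec, "reconstruct", c("window", "zero_pad_factor"))
  ana <- raw$analyze %||% list()
  check_keys(ana, "analyze", c("min_prominence", "noise_region"))

  structure(list(
    ions = ions, cell = cell, amplifier = amp, noise = noise, plan = plan,
    reconstruct = list(window = rec$window %||% "rectangular",
                       zero_pad_factor = rec$zero_pad_factor %||% 8),
    analyze = list(min_prominence = ana$min_prominence %||% 0.1,
                   noise_region = ana$noise_region),
    seed = seed, version = raw$version %||% "1"
  ), class = "ftims_config")
}

check_keys <- function(x, where, allowed) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(paste0("unknown key(s) in `", where, "`: ",
                 paste(extra, collapse = ", ")),
          class = "ftims_error_config")
  }
  invisible(x)
}

#' Run simulate -> reconstruct -> analyze from a configuration
#'
#' @param config An `ftims_config` from [read_run_config()].
#' @return List with `interferogram` (or `trace` for single-gate plans),
#'   `spectrum`, and `peaks` (the [analyze_spectrum()] table); single-gate
#'   runs analyse the arrival trace directly as a spectrum-like table.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$plan)) {
    abort("config has no `plan` section", class = "ftims_error_config")
  }
  if (config$plan$kind == "single_gate") {
    trace <- simulate_single_gate(config$plan, config$ions, config$cell,
                                  amplifier(rise_time = 0.1), config$noise)
    sp <- tibble(drift_time_ms = trace$time_ms, intensity = trace$signal)
    class(sp) <- c("ftims_spectrum", class(sp))
    attr(sp, "resolution_bin_ms") <- trace$time_ms[2] - trace$time_ms[1]
    peaks <- analyze_spectrum(sp, config$cell,
                              config$analyze$min_prominence,
                              config$analyze$noise_region)
    return(list(trace = trace, spectrum = sp, peaks = peaks))
  }
  ig <- if (config$plan$kind == "swept") {
    rec <- simulate_swept(config$plan, config$ions, config$cell, config$noise)
    swept_to_interferogram(rec, f_step = 5)
  } else {
    simulate_interferogram(config$plan, config$ions, config$cell, config$noise)
  }
  sp <- reconstruct_spectrum(ig, config$reconstruct$window,
                             config$reconstruct$zero_pad_factor)
  peaks <- analyze_spectrum(sp, config$cell, config$analyze$min_prominence,
                            config$analyze$noise_region)
  list(interferogram = ig, spectrum = sp, peaks = peaks)
}
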