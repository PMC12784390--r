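#' Write / read an interferogram as CSV
#'
#' Plain comma-separated text with mandatory header
#' `frequency_hz,signal`, `.` decimal, UTF-8. Values are written with
#' 15 significant digits so a write/read round trip is exact to well
#' beyond 12 significant digits. A JSON metadata sidecar
#' (`<path>.json`) records the acquisition parameters and seed when
#' present.
#'
#' @param ig An `ftims_interferogram` (or tibble with the two columns).
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar? Default `TRUE` when
#'   metadata is attached.
#' @return `path`, invisibly.
#' @export
write_interferogram <- function(ig, path, sidecar = TRUE) {
  if (!all(c("frequency_hz", "signal") %in% names(ig))) {
    abort("`ig` must have columns frequency_hz and signal",
          class = "ftims_error_io")
  }
  readr::write_csv(tibble(frequency_hz = ig$frequency_hz, signal = ig$signal),
                   path)
  meta <- attr(ig, "meta")
  if (sidecar && !is.null(meta)) {
    jsonlite::write_json(c(list(schema = "ftims/interferogram/1"), meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_interferogram
#' @return For `read_interferogram()`: an `ftims_interferogram`.
#' @export
read_interferogram <- function(path) {
  df <- read_checked_csv(path, c("frequency_hz", "signal"))
  f <- df$frequency_hz
  if (any(diff(f) <= 0)) {
    abort("frequency grid must be strictly increasing",
          class = "ftims_error_io")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(f_step = stats::median(diff(f)))
  }
  new_interferogram(f, df$signal, meta = meta)
}

#' Write / read a mobility spectrum as CSV
#'
#' Columns `drift_time_ms,intensity`; same dialect and sidecar convention
#' as [write_interferogram()].
#'
#' @param spectrum An `ftims_spectrum`.
#' @param path CSV path.
#' @param sidecar Write JSON metadata (window, padding, axis parameters)?
#' @return `path`, invisibly; for `read_spectrum()` an `ftims_spectrum`.
#' @export
write_spectrum <- function(spectrum, path, sidecar = TRUE) {
  if (!all(c("drift_time_ms", "intensity") %in% names(spectrum))) {
    abort("`spectrum` must have columns drift_time_ms and intensity",
          class = "ftims_error_io")
  }
  readr::write_csv(tibble(drift_time_ms = spectrum$drift_time_ms,
                          intensity = spectrum$intensity), path)
  if (sidecar) {
    meta <- list(schema = "ftims/spectrum/1",
                 f_step = attr(spectrum, "f_step"),
                 f_min = attr(spectrum, "f_min"),
                 f_max = attr(spectrum, "f_max"),
                 window = attr(spectrum, "window"),
                 zero_pad_factor = attr(spectrum, "zero_pad_factor"),
                 n_data = attr(spectrum, "n_data"),
                 bin_ms = attr(spectrum, "bin_ms"),
                 resolution_bin_ms = attr(spectrum, "resolution_bin_ms"))
    meta <- meta[!vapply(meta, is.null, logical(1))]
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read_checked_csv(path, c("drift_time_ms", "intensity"))
  if (any(diff(df$drift_time_ms) <= 0)) {
    abort("drift-time axis must be strictly increasing",
          class = "ftims_error_io")
  }
  out <- tibble(drift_time_ms = df$drift_time_ms, intensity = df$intensity)
  class(out) <- c("ftims_spectrum", class(out))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    for (key in c("f_step", "f_min", "f_max", "window", "zero_pad_factor",
                  "n_data", "bin_ms", "resolution_bin_ms")) {
      if (!is.null(meta[[key]])) attr(out, key) <- meta[[key]]
    }
  }
  out
}

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ftims_error_io")
  }
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) abort(paste0("could not parse CSV: ", conditionMessage(e)),
                              class = "ftims_error_io"))
  if (!identical(names(df), cols)) {
    abort(paste0("expected header `", paste(cols, collapse = ","), "`"),
          class = "ftims_error_io")
  }
  if (nrow(df) == 0) abort("no data rows", class = "ftims_error_io")
  if (any(vapply(df, function(x) any(is.na(x)), logical(1)))) {
    abort("non-numeric or missing values in data rows",
          class = "ftims_error_io")
  }
  df
}

#' Built-in test mixtures
#'
#' Ready-made ion mixtures on the default standards-calibrated cell:
#' `"rip"` -- a single reactant-ion peak at 20 ms; `"txa4"` -- the four
#' tetraalkylammonium standards (T3A, T4A, T5A, T6A at 30.11, 35.06,
#' 40.33 and 45.49 ms); `"bench9"` -- all nine benchmark compounds of
#' [reference_compounds()] at their single-gate drift times. Intrinsic
#' widths are set so that an instrument-limited measurement shows a
#' resolving power of about 80 (`sigma = td / 80 / 2.3548`), typical of a
#' well-tuned bench drift tube.
#'
#' @param name One of `"rip"`, `"txa4"`, `"bench9"`.
#' @return List with elements `ions` (mixture tibble) and `cell`
#'   ([drift_cell()]).
#' @examples
#' fixture_mixture("txa4")$ions
#' @export
fixture_mixture <- function(name) {
  known <- c("rip", "txa4", "bench9")
  if (!is.character(name) || length(name) != 1 || !(name %in% known)) {
    abort(paste0("unknown fixture; available: ",
                 paste(known, collapse = ", ")),
          class = "ftims_error_io")
  }
  cell <- drift_cell()
  ref <- reference_compounds()
  sig <- function(td) td / 80 / 2.3548
  ions <- switch(name,
    rip = ion_species("RIP", td = 20, abundance = 1, sigma = sig(20)),
    txa4 = {
      txa <- ref[ref$compound %in% c("T3A", "T4A", "T5A", "T6A"), ]
      bind_rows(pmap(list(txa$compound, txa$td_sg), function(nm, td) {
        ion_species(nm, td = td, abundance = 1, sigma = sig(td))
      }))
    },
    bench9 = bind_rows(pmap(list(ref$compound, ref$td_sg), function(nm, td) {
      ion_species(nm, td = td, abundance = 1, sigma = sig(td))
    }))
  )
  list(ions = ions, cell = cell)
}
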