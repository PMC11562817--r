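# Delimited-text I/O. All formats are plain CSV with `#` comment lines;
# spectral files carry their metadata in `# key=value` header lines.

read_commented_csv <- function(path) {
  readr::read_csv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
}

header_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  kv <- kv[vapply(kv, length, integer(1)) == 3L]
  setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) m[2], character(1))
  )
}

#' Read / write a spectral power distribution
#'
#' CSV with header columns `wavelength_nm`, `irradiance_W_m2_nm`; lines
#' starting with `#` are comments. Written SPDs are on the canonical grid.
#'
#' @param path File path.
#' @return `read_spd` returns an `spd`; `write_spd` returns `path`
#'   invisibly.
#' @export
read_spd <- function(path) {
  df <- read_commented_csv(path)
  if (!all(c("wavelength_nm", "irradiance_W_m2_nm") %in% names(df))) {
    abort(sprintf(
      "%s: expected columns `wavelength_nm`, `irradiance_W_m2_nm`.", path
    ))
  }
  as_spd(df)
}

#' @rdname read_spd
#' @param x An `spd`.
#' @export
write_spd <- function(x, path) {
  x <- resample_to_canonical(as_spd(x))
  writeLines("# alphaopix spectral power distribution (canonical 1-nm grid)", path)
  readr::write_csv(
    tibble::tibble(
      wavelength_nm = x$wavelength_nm,
      irradiance_W_m2_nm = x$irradiance
    ),
    path,
    append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' Read / write a spectral sensitivity
#'
#' CSV with columns `wavelength_nm`, `weight` and metadata header lines
#' `# lambda_max=`, `# chromophore=`, `# flavor=`, `# filtered=`.
#'
#' @param path File path.
#' @return `read_sensitivity` returns a `spectral_sensitivity`;
#'   `write_sensitivity` returns `path` invisibly.
#' @export
read_sensitivity <- function(path) {
  meta <- header_meta(path)
  df <- read_commented_csv(path)
  if (!all(c("wavelength_nm", "weight") %in% names(df))) {
    abort(sprintf("%s: expected columns `wavelength_nm`, `weight`.", path))
  }
  new_sensitivity(
    weight = df$weight,
    lambda_max = as.numeric(meta$lambda_max %||% NA),
    flavor = meta$flavor %||% "quantal",
    filtered = identical(meta$filtered, "TRUE"),
    chromophore = meta$chromophore %||% NA_character_,
    wavelength_nm = df$wavelength_nm
  )
}

#' @rdname read_sensitivity
#' @param sens A `spectral_sensitivity`.
#' @export
write_sensitivity <- function(sens, path) {
  stopifnot(is_sensitivity(sens))
  writeLines(c(
    sprintf("# lambda_max=%s", format(sens_attr(sens, "lambda_max"))),
    sprintf("# chromophore=%s", sens_attr(sens, "chromophore")),
    sprintf("# flavor=%s", sens_attr(sens, "flavor")),
    sprintf("# filtered=%s", isTRUE(sens_attr(sens, "filtered")))
  ), path)
  readr::write_csv(
    tibble::tibble(wavelength_nm = sens$wavelength_nm, weight = sens$weight),
    path,
    append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' Read / write a lens transmission curve
#'
#' Raw input files have `wavelength_nm` and one of `transmission_pct` or
#' `relative_absorbance`; [read_lens()] harmonizes them onto the canonical
#' grid. Harmonized output carries a `# lambda50=` header.
#'
#' @param path File path.
#' @param harmonize Apply [harmonize_transmission()] to raw input (default
#'   `TRUE`); set `FALSE` only for files already on the canonical grid.
#' @return `read_lens` returns a `lens_transmission`; `write_lens`
#'   returns `path` invisibly.
#' @export
read_lens <- function(path, harmonize = TRUE) {
  df <- read_commented_csv(path)
  if (!"wavelength_nm" %in% names(df)) {
    abort(sprintf("%s: expected a `wavelength_nm` column.", path))
  }
  if ("transmission_pct" %in% names(df)) {
    df$transmission <- df$transmission_pct
  }
  if (!harmonize) {
    if (!is_canonical(df$wavelength_nm)) {
      abort(sprintf("%s: not on the canonical grid; use harmonize = TRUE.", path))
    }
    return(new_lens(df$transmission / max(df$transmission)))
  }
  harmonize_transmission(df)
}

#' @rdname read_lens
#' @param lens A `lens_transmission`.
#' @export
write_lens <- function(lens, path) {
  stopifnot(is_lens(lens))
  writeLines(sprintf("# lambda50=%s", format(lens_lambda50(lens))), path)
  readr::write_csv(
    tibble::tibble(
      wavelength_nm = lens$wavelength_nm,
      transmission_pct = 100 * lens$transmission
    ),
    path,
    append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' Read a dose-response table
#'
#' CSV with columns `stimulus_id`, `wavelength_nm`, `log10_photon_flux`,
#' `response`.
#'
#' @param path File path.
#' @return A tibble ready for [estimate_lambda_max()].
#' @export
read_dose_response <- function(path) {
  df <- read_commented_csv(path)
  need <- c("stimulus_id", "wavelength_nm", "log10_photon_flux", "response")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a sensor count log
#'
#' CSV with columns `stimulus_id`, `gain`, `integration_ms` and the ten
#' channel columns `ch415` ... `ch910`, `clear`.
#'
#' @param path File path.
#' @return A tibble ready for [normalize_counts()].
#' @export
read_sensor_log <- function(path) {
  df <- read_commented_csv(path)
  need <- c("stimulus_id", "gain", "integration_ms", sensor_channels)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(missing, collapse = ", ")))
  }
  df
}
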