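#' Canonical wavelength grid
#'
#' All spectral quantities in the package live on a common 1-nm grid from
#' 300 to 800 nm. Integrals are rectangular sums with \eqn{\Delta\lambda =
#' 1} nm on this grid.
#'
#' @return Integer vector of wavelengths (nm).
#' @export
canonical_grid <- function() {
  300:800
}

is_canonical <- function(wl) {
  length(wl) == 501L && identical(as.numeric(wl), as.numeric(300:800))
}

new_spd <- function(wavelength_nm, irradiance) {
  out <- tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    irradiance = as.numeric(irradiance)
  )
  class(out) <- c("spd", class(out))
  out
}

#' Construct a spectral power distribution
#'
#' An SPD is a tibble with columns `wavelength_nm` (strictly increasing, nm)
#' and `irradiance` (spectral irradiance, W m^-2 nm^-1, non-negative).
#'
#' @param wavelength_nm Wavelengths in nm, strictly increasing.
#' @param irradiance Spectral irradiance in W m^-2 nm^-1; non-negative,
#'   finite, same length as `wavelength_nm`.
#' @return A tibble of class `spd`.
#' @examples
#' spd(400:700, rep(0.01, 301))
#' @export
spd <- function(wavelength_nm, irradiance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  irradiance <- as.numeric(irradiance)
  if (length(wavelength_nm) != length(irradiance)) {
    abort("`wavelength_nm` and `irradiance` must have the same length.")
  }
  if (length(wavelength_nm) < 2L) {
    abort("an SPD needs at least 2 points.")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    abort("`wavelength_nm` must be strictly increasing.")
  }
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    abort("`irradiance` must be finite and non-negative.")
  }
  new_spd(wavelength_nm, irradiance)
}

#' Coerce a data frame to an SPD
#'
#' Accepts the package's on-disk column names (`irradiance_W_m2_nm`) as well
#' as the in-memory name `irradiance`.
#'
#' @param x A data frame with a `wavelength_nm` column and one irradiance
#'   column.
#' @return A tibble of class `spd`.
#' @export
as_spd <- function(x) {
  if (is_spd(x)) {
    return(x)
  }
  x <- as.data.frame(x)
  if (!"wavelength_nm" %in% names(x)) {
    abort("`x` must have a `wavelength_nm` column.")
  }
  val_col <- intersect(c("irradiance", "irradiance_W_m2_nm"), names(x))
  if (length(val_col) == 0L) {
    abort("`x` must have an `irradiance` or `irradiance_W_m2_nm` column.")
  }
  spd(x$wavelength_nm, x[[val_col[1]]])
}

#' @rdname as_spd
#' @export
is_spd <- function(x) {
  inherits(x, "spd")
}

assert_canonical_spd <- function(x, arg = "spd") {
  if (!is_spd(x)) {
    abort(sprintf("`%s` must be an spd object (see `spd()`).", arg))
  }
  if (!is_canonical(x$wavelength_nm)) {
    abort(sprintf(
      "`%s` must be on the canonical 1-nm grid; see `resample_to_canonical()`.",
      arg
    ))
  }
  invisible(x)
}

#' Resample an SPD onto the canonical grid
#'
#' Linear interpolation onto the 1-nm grid over 300-800 nm. Wavelengths
#' outside the supplied support are zero-filled, never extrapolated.
#'
#' @param x An `spd` (any strictly increasing grid).
#' @return An `spd` on the canonical grid.
#' @examples
#' resample_to_canonical(spd(seq(400, 700, 5), rep(1, 61)))
#' @export
resample_to_canonical <- function(x) {
  x <- as_spd(x)
  if (is_canonical(x$wavelength_nm)) {
    return(x)
  }
  grid <- canonical_grid()
  in_range <- x$wavelength_nm >= 300 & x$wavelength_nm <= 800
  if (sum(in_range) < 2L) {
    abort("need at least 2 points within [300, 800] nm to resample.")
  }
  y <- approx(
    x$wavelength_nm, x$irradiance,
    xout = grid, method = "linear", rule = 1
  )$y
  y[is.na(y)] <- 0
  new_spd(grid, pmax(y, 0))
}

#' Photopic illuminance of an SPD
#'
#' Illuminance in lux: \eqn{E_v = K_m \sum_\lambda E_{e,\lambda}(\lambda)
#' V(\lambda) \Delta\lambda}, with \eqn{K_m = 683} lm/W and the CIE 1924
#' photopic luminous efficiency function \eqn{V(\lambda)}.
#'
#' @param x An `spd` on the canonical grid.
#' @return Illuminance in lux (non-negative scalar).
#' @examples
#' photopic_illuminance(gaussian_spd(555, 5, scale = 0.1))
#' @export
photopic_illuminance <- function(x) {
  x <- resample_to_canonical(as_spd(x))
  .k_m * sum(x$irradiance * vlambda())
}

#' Rescale an SPD to a target photopic illuminance
#'
#' @param x An `spd`.
#' @param target_lux Desired photopic illuminance (lux, >= 0).
#' @return The rescaled `spd` on the canonical grid.
#' @details A warning is raised when the light is nearly invisible to
#'   \eqn{V(\lambda)} (for example a 365-nm narrowband source), because the
#'   required scale factor is then extreme and small calibration errors in
#'   the short-wavelength tail of \eqn{V(\lambda)} dominate the result.
#' @export
scale_to_illuminance <- function(x, target_lux) {
  x <- resample_to_canonical(as_spd(x))
  if (target_lux == 0) {
    return(new_spd(x$wavelength_nm, rep(0, nrow(x))))
  }
  lux <- photopic_illuminance(x)
  if (lux <= 0) {
    abort("cannot rescale: the SPD has zero photopic illuminance.")
  }
  total <- sum(x$irradiance)
  if (total > 0 && lux / (.k_m * total) < 1e-3) {
    warn(paste(
      "SPD is nearly invisible to V(lambda);",
      "the illuminance-matched scale factor is extreme."
    ))
  }
  new_spd(x$wavelength_nm, x$irradiance * (target_lux / lux))
}

#' Convert energy spectral irradiance to photon spectral flux
#'
#' Per-wavelength conversion by \eqn{\lambda / (h c)} with unit conversion
#' from m^-2 to cm^-2, i.e. photons cm^-2 s^-1 nm^-1.
#'
#' @param x An `spd` on the canonical grid.
#' @return A tibble with `wavelength_nm` and `photon_flux`
#'   (photons cm^-2 s^-1 nm^-1).
#' @export
energy_to_photon_flux <- function(x) {
  x <- resample_to_canonical(as_spd(x))
  lam_m <- x$wavelength_nm * 1e-9
  tibble::tibble(
    wavelength_nm = x$wavelength_nm,
    photon_flux = x$irradiance * lam_m / (.planck_h * .light_c) * 1e-4
  )
}

#' Convert photon spectral flux back to energy spectral irradiance
#'
#' Inverse of [energy_to_photon_flux()].
#'
#' @param x A data frame with `wavelength_nm` and `photon_flux`
#'   (photons cm^-2 s^-1 nm^-1).
#' @return An `spd` on the same grid.
#' @export
photon_to_energy_flux <- function(x) {
  if (!all(c("wavelength_nm", "photon_flux") %in% names(x))) {
    abort("`x` must have `wavelength_nm` and `photon_flux` columns.")
  }
  lam_m <- x$wavelength_nm * 1e-9
  new_spd(
    x$wavelength_nm,
    x$photon_flux * 1e4 * (.planck_h * .light_c) / lam_m
  )
}

#' @export
autoplot.spd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$irradiance)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(
      x = "Wavelength (nm)",
      y = expression(Spectral ~ irradiance ~ (W ~ m^-2 ~ nm^-1))
    ) +
    ggplot2::theme_minimal()
}
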