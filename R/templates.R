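# Visual pigment absorbance templates.
#
# The A1 (retinal-1) nomogram of Govardovskii et al. (2000, Vis. Neurosci.
# 17:509-528): an alpha band parameterised in x = lambda_max / lambda plus a
# Gaussian beta band whose position and width scale with lambda_max.

.gov_validity <- c(330, 620)

# Template evaluated at arbitrary wavelengths; returns unnormalized
# alpha + beta absorbance (quantal sensitivity).
govardovskii_eval <- function(wavelength_nm, lambda_max) {
  x <- lambda_max / wavelength_nm
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (
    exp(69.7 * (a - x)) +
      exp(28 * (0.922 - x)) +
      exp(-14.9 * (1.104 - x)) +
      0.674
  )
  beta_peak <- 189 + 0.315 * lambda_max
  beta_band <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelength_nm - beta_peak) / beta_band)^2)
  alpha + beta
}

new_sensitivity <- function(weight,
                            lambda_max,
                            flavor,
                            filtered,
                            chromophore = NA_character_,
                            wavelength_nm = canonical_grid()) {
  weight <- weight / max(weight)
  out <- tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    weight = as.numeric(weight)
  )
  class(out) <- c("spectral_sensitivity", class(out))
  attr(out, "lambda_max") <- lambda_max
  attr(out, "flavor") <- flavor
  attr(out, "filtered") <- filtered
  attr(out, "chromophore") <- chromophore
  out
}

#' @rdname govardovskii_template
#' @param x Object to test.
#' @export
is_sensitivity <- function(x) {
  inherits(x, "spectral_sensitivity")
}

sens_attr <- function(x, what) {
  attr(x, what, exact = TRUE)
}

#' Pigment spectral sensitivity from the Govardovskii A1 nomogram
#'
#' Evaluates the alpha + beta band vitamin-A1 pigment template at the given
#' peak wavelength on the canonical grid and renormalizes to unit peak. The
#' result is a quantal, unfiltered sensitivity; combine with a lens via
#' [in_vivo_sensitivity()] and convert with [quantal_to_energy()] for use
#' in energy-irradiance weighting.
#'
#' @param lambda_max Pigment peak wavelength (nm), within 330-620 nm.
#' @param chromophore Retinaldehyde isoform tag carried as metadata,
#'   `"11-cis"` (default) or `"9-cis"`.
#' @return A `spectral_sensitivity` tibble (`wavelength_nm`, `weight`) with
#'   attributes `lambda_max`, `flavor = "quantal"`, `filtered = FALSE` and
#'   `chromophore`.
#' @examples
#' mel <- govardovskii_template(480)
#' mel$wavelength_nm[which.max(mel$weight)]
#' @export
govardovskii_template <- function(lambda_max, chromophore = "11-cis") {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
    lambda_max < .gov_validity[1] || lambda_max > .gov_validity[2]) {
    abort(sprintf(
      "`lambda_max` must be a single value within [%d, %d] nm.",
      .gov_validity[1], .gov_validity[2]
    ))
  }
  chromophore <- match.arg(chromophore, c("11-cis", "9-cis"))
  w <- govardovskii_eval(canonical_grid(), lambda_max)
  new_sensitivity(
    weight = w,
    lambda_max = lambda_max,
    flavor = "quantal",
    filtered = FALSE,
    chromophore = chromophore
  )
}

#' Convert a quantal sensitivity to energy flavor
#'
#' A pigment template expresses the probability of photon capture (quantal
#' sensitivity). Weighting an energy spectral irradiance requires the
#' energy-based function, obtained by multiplying the quantal weights by
#' \eqn{\lambda} (longer-wavelength photons carry less energy, so equal
#' energy delivers more of them) and re-normalizing to unit peak. The peak
#' shifts a few nm to longer wavelengths.
#'
#' @param sens A quantal `spectral_sensitivity`.
#' @return The energy-flavored sensitivity. Applying it to an
#'   already-energy-flavored input warns and returns the input unchanged.
#' @export
quantal_to_energy <- function(sens) {
  stopifnot(is_sensitivity(sens))
  if (identical(sens_attr(sens, "flavor"), "energy")) {
    warn("sensitivity is already energy-flavored; returning unchanged.")
    return(sens)
  }
  new_sensitivity(
    weight = sens$weight * sens$wavelength_nm,
    lambda_max = sens_attr(sens, "lambda_max"),
    flavor = "energy",
    filtered = sens_attr(sens, "filtered"),
    chromophore = sens_attr(sens, "chromophore"),
    wavelength_nm = sens$wavelength_nm
  )
}

#' Correct a 9-cis retinal peak wavelength to the 11-cis value
#'
#' Action spectroscopy performed with the commercially accessible 9-cis
#' retinaldehyde chromophore yields pigment peaks blue-shifted relative to
#' the physiological 11-cis isoform; the correction adds 16 nm.
#'
#' @param lambda_max Peak wavelength (nm) measured with 9-cis retinal.
#' @param chromophore Isoform the measurement was made with; must be
#'   `"9-cis"` (passing `"11-cis"` is refused rather than silently
#'   double-corrected).
#' @return The 11-cis peak wavelength (nm), carrying a `chromophore`
#'   attribute set to `"11-cis"`.
#' @examples
#' apply_chromophore_shift(465)
#' @export
apply_chromophore_shift <- function(lambda_max, chromophore = "9-cis") {
  if (!identical(chromophore, "9-cis")) {
    abort("input is already 11-cis; refusing to apply the 9-cis correction.")
  }
  structure(lambda_max + 16, chromophore = "11-cis")
}

#' @export
autoplot.spectral_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$weight)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(
      x = "Wavelength (nm)",
      y = "Relative sensitivity",
      subtitle = sprintf(
        "lambda_max %s nm, %s%s",
        format(sens_attr(object, "lambda_max")),
        sens_attr(object, "flavor"),
        if (isTRUE(sens_attr(object, "filtered"))) ", lens-filtered" else ""
      )
    ) +
    ggplot2::theme_minimal()
}
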