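# Pre-receptoral filtering: harmonization of ocular-media (lens)
# transmission curves and their combination with pigment templates.

new_lens <- function(transmission, source_count = 1L,
                     wavelength_nm = canonical_grid()) {
  out <- tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    transmission = as.numeric(transmission)
  )
  class(out) <- c("lens_transmission", class(out))
  attr(out, "lambda50") <- compute_lambda50(out$wavelength_nm, out$transmission)
  attr(out, "source_count") <- as.integer(source_count)
  out
}

#' @rdname harmonize_transmission
#' @param x Object to test.
#' @export
is_lens <- function(x) {
  inherits(x, "lens_transmission")
}

# shortest wavelength at which transmission first reaches 0.5, with linear
# interpolation between grid points
compute_lambda50 <- function(wl, tr) {
  above <- which(tr >= 0.5)
  if (length(above) == 0L) {
    return(NA_real_)
  }
  i <- above[1]
  if (i == 1L) {
    return(wl[1])
  }
  wl[i - 1] + (0.5 - tr[i - 1]) / (tr[i] - tr[i - 1]) * (wl[i] - wl[i - 1])
}

#' Lens lambda-50
#'
#' The minimum wavelength at which the lens transmits 50% of incident
#' light, the field's one-number summary of short-wavelength lens filtering.
#'
#' @param lens A `lens_transmission`.
#' @return Wavelength in nm (NA if the curve never reaches 0.5).
#' @export
lens_lambda50 <- function(lens) {
  stopifnot(is_lens(lens))
  attr(lens, "lambda50", exact = TRUE)
}

#' Convert relative absorbance to percent transmission
#'
#' \eqn{T = 100 \times 10^{-A}} per wavelength. Negative absorbances
#' (possible in baseline-subtracted raw data) give transmissions above
#' 100%, which the harmonization step later normalizes away.
#'
#' @param relative_absorbance Numeric vector of relative absorbance values.
#' @return Percent transmission, same length.
#' @examples
#' absorbance_to_transmission(c(0, 1, 0.301))
#' @export
absorbance_to_transmission <- function(relative_absorbance) {
  if (any(!is.finite(relative_absorbance))) {
    abort("`relative_absorbance` must be finite.")
  }
  100 * 10^(-relative_absorbance)
}

#' Harmonize a raw ocular transmission curve
#'
#' Applies the standardisation pipeline for published lens transmission
#' data, in order: spline interpolation onto a 1-nm grid (interpolating
#' cubic splines when fewer than 50 raw points are available, cubic
#' smoothing splines with 50 knots otherwise); normalization to unit
#' maximum; extension to 800 nm holding the last value; extension to short
#' wavelengths along the slope of the first 3 interpolated values; negative
#' values clipped to 0 and values above 1 clipped to 1.
#'
#' @param data Data frame with a `wavelength_nm` column and either a
#'   `transmission` column (any positive scale: fraction or percent) or a
#'   `relative_absorbance` column.
#' @return A `lens_transmission` tibble on the canonical grid with
#'   attributes `lambda50` and `source_count = 1`.
#' @examples
#' raw <- tibble::tibble(
#'   wavelength_nm = seq(350, 700, 12),
#'   transmission = 100 * plogis((seq(350, 700, 12) - 420) / 15)
#' )
#' lens <- harmonize_transmission(raw)
#' lens_lambda50(lens)
#' @export
harmonize_transmission <- function(data) {
  data <- as.data.frame(data)
  if (!"wavelength_nm" %in% names(data)) {
    abort("`data` must have a `wavelength_nm` column.")
  }
  if ("transmission" %in% names(data)) {
    value <- data$transmission
  } else if ("relative_absorbance" %in% names(data)) {
    value <- absorbance_to_transmission(data$relative_absorbance)
  } else {
    abort("`data` needs a `transmission` or `relative_absorbance` column.")
  }
  wl <- data$wavelength_nm
  ord <- order(wl)
  wl <- wl[ord]
  value <- value[ord]
  n <- length(wl)
  if (n < 4L || diff(range(wl)) < 100) {
    abort("need at least 4 raw points spanning at least 100 nm.")
  }

  grid_in <- seq(ceiling(min(wl)), floor(max(wl)), by = 1)
  if (n < 50L) {
    fit <- spline(wl, value, xout = grid_in, method = "fmm")$y
  } else {
    sm <- smooth.spline(wl, value, nknots = 50)
    fit <- predict(sm, grid_in)$y
  }

  # normalize before extending so the extensions inherit the unit scale
  fit <- fit / max(fit)

  grid <- canonical_grid()
  out <- rep(NA_real_, length(grid))
  out[match(grid_in, grid)] <- fit

  # long side: hold last value to 800 nm
  last_idx <- match(max(grid_in), grid)
  if (last_idx < length(grid)) {
    out[(last_idx + 1):length(grid)] <- fit[length(fit)]
  }
  # short side: extend along the slope of the first 3 interpolated values
  first_idx <- match(min(grid_in), grid)
  if (first_idx > 1L) {
    slope <- (fit[3] - fit[1]) / (grid_in[3] - grid_in[1])
    out[1:(first_idx - 1)] <- fit[1] + slope * (grid[1:(first_idx - 1)] - grid_in[1])
  }

  out <- pmin(pmax(out, 0), 1)
  new_lens(out)
}

#' Average several harmonized lens curves
#'
#' Pointwise mean of the input curves, re-normalized to unit maximum; used
#' when multiple published sources exist for one species.
#'
#' @param curves List of `lens_transmission` objects on the canonical grid.
#' @return A `lens_transmission` with `source_count` equal to the number of
#'   inputs.
#' @export
average_sources <- function(curves) {
  if (length(curves) == 0L) {
    abort("`curves` must contain at least one lens curve.")
  }
  stopifnot(all(vapply(curves, is_lens, logical(1))))
  m <- vapply(curves, function(x) x$transmission, numeric(501))
  avg <- rowMeans(m)
  new_lens(avg / max(avg), source_count = length(curves))
}

#' Combine a pigment template with lens filtering
#'
#' In-vivo spectral sensitivity is the pointwise product of the (unfiltered)
#' pigment sensitivity and lens transmission, re-normalized to unit peak.
#'
#' @param template An unfiltered `spectral_sensitivity`.
#' @param lens A `lens_transmission` on the canonical grid.
#' @return The filtered `spectral_sensitivity` (same flavor).
#' @export
in_vivo_sensitivity <- function(template, lens) {
  stopifnot(is_sensitivity(template), is_lens(lens))
  if (isTRUE(sens_attr(template, "filtered"))) {
    abort("template is already lens-filtered; refusing to filter twice.")
  }
  new_sensitivity(
    weight = template$weight * lens$transmission,
    lambda_max = sens_attr(template, "lambda_max"),
    flavor = sens_attr(template, "flavor"),
    filtered = TRUE,
    chromophore = sens_attr(template, "chromophore"),
    wavelength_nm = template$wavelength_nm
  )
}

#' Parametric logistic lens model
#'
#' A logistic transmission curve \eqn{1/(1+\exp(-(\lambda-\lambda_{50})/w))}
#' normalized to unit maximum; a documented synthetic stand-in used for
#' species whose digitized lens curves are not packaged.
#'
#' @param lambda50 Wavelength of half-maximal transmission (nm), 310-500.
#' @param width Logistic width parameter (nm, > 0); smaller is steeper.
#' @return A `lens_transmission` on the canonical grid.
#' @examples
#' parametric_lens(400, 10)
#' @export
parametric_lens <- function(lambda50, width = 10) {
  if (lambda50 < 310 || lambda50 > 500) {
    abort("`lambda50` must be within [310, 500] nm.")
  }
  if (width <= 0) {
    abort("`width` must be positive.")
  }
  tr <- plogis((canonical_grid() - lambda50) / width)
  new_lens(tr / max(tr))
}

#' @export
autoplot.lens_transmission <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$wavelength_nm, .data$transmission)
  ) +
    ggplot2::geom_line(...) +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "Transmission (fraction)",
      subtitle = sprintf(
        "lambda50 = %s nm", format(round(lens_lambda50(object), 1))
      )
    ) +
    ggplot2::theme_minimal()
}
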