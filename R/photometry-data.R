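# Bundled photometric reference functions.
#
# V(lambda): CIE 1924 2-degree photopic luminous efficiency function,
# tabulated at 5 nm (380-780 nm) and spline-interpolated to the canonical
# 1-nm grid; zero outside the tabulated range. Peak value 1 at 555 nm.
#
# D65: CIE standard daylight illuminant, relative spectral power at 5 nm
# (300-800 nm, 100 at 560 nm), spline-interpolated to 1 nm and rescaled to
# unit maximum. Every quantity in the package that uses D65 is a ratio in
# which its absolute scale cancels.

.vlambda_5nm <- c(
  # 380..780 nm step 5
  0.00004, 0.00006, 0.00012, 0.00022, 0.00040, 0.00064, 0.00121, 0.00218,
  0.00400, 0.00730, 0.01160, 0.01684, 0.02300, 0.02980, 0.03800, 0.04800,
  0.06000, 0.07390, 0.09098, 0.11260, 0.13902, 0.16930, 0.20802, 0.25860,
  0.32300, 0.40730, 0.50300, 0.60820, 0.71000, 0.79320, 0.86200, 0.91485,
  0.95400, 0.98030, 0.99495, 1.00000, 0.99500, 0.97860, 0.95200, 0.91540,
  0.87000, 0.81630, 0.75700, 0.69490, 0.63100, 0.56680, 0.50300, 0.44120,
  0.38100, 0.32100, 0.26500, 0.21700, 0.17500, 0.13820, 0.10700, 0.08160,
  0.06100, 0.04458, 0.03200, 0.02320, 0.01700, 0.01192, 0.00821, 0.00572,
  0.00410, 0.00293, 0.00209, 0.00148, 0.00105, 0.00074, 0.00052, 0.00036,
  0.00025, 0.00017, 0.00012, 0.00008, 0.00006, 0.00004, 0.00003, 0.00002,
  0.00001
)

.d65_5nm <- c(
  # 300..800 nm step 5, relative power (100 at 560 nm)
  0.0341, 1.6643, 3.2945, 11.7652, 20.2360, 28.6447, 37.0535, 38.5011,
  39.9488, 42.4302, 44.9117, 45.7750, 46.6383, 49.3637, 52.0891, 51.0323,
  49.9755, 52.3118, 54.6482, 68.7015, 82.7549, 87.1204, 91.4860, 92.4589,
  93.4318, 90.0570, 86.6823, 95.7736, 104.8650, 110.9360, 117.0080,
  117.4100, 117.8120, 116.3360, 114.8610, 115.3920, 115.9230, 112.3670,
  108.8110, 109.0820, 109.3540, 108.5780, 107.8020, 106.2960, 104.7900,
  106.2390, 107.6890, 106.0470, 104.4050, 104.2250, 104.0460, 102.0230,
  100.0000, 98.1671, 96.3342, 96.0611, 95.7880, 92.2368, 88.6856, 89.3459,
  90.0062, 89.8026, 89.5991, 88.6489, 87.6987, 85.4936, 83.2886, 83.4939,
  83.6992, 81.8630, 80.0268, 80.1207, 80.2146, 81.2462, 82.2778, 80.2810,
  78.2842, 74.0027, 69.7213, 70.6652, 71.6091, 72.9790, 74.3490, 67.9765,
  61.6040, 65.7448, 69.8856, 72.4863, 75.0870, 69.3398, 63.5927, 55.0054,
  46.4182, 56.6118, 66.8054, 65.0941, 63.3828, 63.8434, 64.3040, 61.8779,
  59.4519
)

.photometry_cache <- new.env(parent = emptyenv())

interp_5nm <- function(wl5, val5) {
  grid <- canonical_grid()
  y <- rep(0, length(grid))
  inside <- grid >= min(wl5) & grid <= max(wl5)
  y[inside] <- spline(wl5, val5, xout = grid[inside], method = "fmm")$y
  pmax(y, 0)
}

#' CIE 1924 photopic luminous efficiency function V(lambda)
#'
#' Tabulated at 1 nm on the canonical grid; dimensionless, peak 1 at
#' 555 nm, zero outside 380-780 nm.
#'
#' @return Numeric vector of length 501 aligned with [canonical_grid()].
#' @export
vlambda <- function() {
  if (is.null(.photometry_cache$vlambda)) {
    v <- interp_5nm(seq(380, 780, 5), .vlambda_5nm)
    v <- v / max(v) # peak exactly 1 (at 555 nm, a table knot)
    .photometry_cache$vlambda <- v
  }
  .photometry_cache$vlambda
}

#' D65 standard daylight, relative spectral power
#'
#' The CIE D65 daylight illuminant on the canonical grid, rescaled to unit
#' maximum. Use [scale_to_illuminance()] to pin it to an absolute photopic
#' illuminance.
#'
#' @param target_lux Optional photopic illuminance (lux) to scale to.
#' @return An `spd` on the canonical grid.
#' @examples
#' d65 <- d65_spd(target_lux = 100)
#' photopic_illuminance(d65)
#' @export
d65_spd <- function(target_lux = NULL) {
  if (is.null(.photometry_cache$d65)) {
    d <- interp_5nm(seq(300, 800, 5), .d65_5nm)
    .photometry_cache$d65 <- d / max(d)
  }
  out <- new_spd(canonical_grid(), .photometry_cache$d65)
  if (!is.null(target_lux)) {
    out <- scale_to_illuminance(out, target_lux)
  }
  out
}

#' V(lambda) as a spectral sensitivity object
#'
#' Convenience wrapper exposing the photopic luminous efficiency function in
#' the same container as photoreceptor sensitivities, e.g. to verify that
#' the D65 alpha-opic efficacy of V(lambda) itself equals 1/683 W/lm.
#'
#' @return A `spectral_sensitivity` (energy flavor, filtered).
#' @export
photopic_sensitivity <- function() {
  new_sensitivity(
    weight = vlambda(),
    lambda_max = 555,
    flavor = "energy",
    filtered = TRUE,
    chromophore = NA_character_
  )
}
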