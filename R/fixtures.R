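# Seeded synthetic generators for every input class: narrowband and
# broadband SPDs, dose-response datasets, sensor count logs, and a
# daylight series. All randomness is controlled by an explicit seed;
# identical arguments and seed give identical output.

#' Gaussian narrowband SPD
#'
#' A narrowband stimulus reconstructed as a normal distribution from its
#' peak wavelength and half width at half maximum
#' (\eqn{\sigma = HWHM / \sqrt{2 \ln 2}}).
#'
#' @param peak_nm Peak wavelength (nm), within the canonical grid.
#' @param hwhm_nm Half width at half maximum (nm).
#' @param scale Peak spectral irradiance (W m^-2 nm^-1).
#' @return An `spd` on the canonical grid.
#' @examples
#' g <- gaussian_spd(460, 10)
#' g$irradiance[g$wavelength_nm == 470] # half the peak
#' @export
gaussian_spd <- function(peak_nm, hwhm_nm, scale = 1) {
  if (peak_nm < 300 || peak_nm > 800) {
    abort("`peak_nm` must lie within the canonical grid (300-800 nm).")
  }
  grid <- canonical_grid()
  # exp(-hwhm^2/s2) = 1/2  =>  s2 = hwhm^2 / ln 2
  sigma2 <- hwhm_nm^2 / log(2)
  new_spd(grid, scale * exp(-(grid - peak_nm)^2 / sigma2))
}

#' Parametric broadband white SPDs
#'
#' Deterministic white-light models standing in for common illuminant
#' classes: a blue-pump + phosphor LED (`"led"`), a multi-peak fluorescent
#' lamp (`"fluorescent"`), and a 4-primary colour-mixed white
#' (`"rgb_mix"`). Matched in photopic lux, these shapes diverge in
#' melanopic content, which is the property they exist to exercise.
#'
#' @param shape One of `"led"`, `"fluorescent"`, `"rgb_mix"`.
#' @param scale Overall linear scale.
#' @return An `spd` on the canonical grid.
#' @export
broadband_white <- function(shape = c("led", "fluorescent", "rgb_mix"),
                            scale = 1) {
  shape <- match.arg(shape)
  g <- function(peak, hwhm, amp) amp * gaussian_spd(peak, hwhm)$irradiance
  v <- switch(shape,
    led = g(450, 12, 1) + g(560, 70, 0.85),
    fluorescent = g(405, 8, 0.25) + g(436, 8, 0.7) + g(487, 8, 0.3) +
      g(546, 8, 1) + g(578, 10, 0.5) + g(611, 8, 0.9) + g(520, 100, 0.15),
    rgb_mix = g(365, 8, 0.3) + g(460, 10, 0.9) + g(525, 12, 1) + g(635, 10, 0.9)
  )
  new_spd(canonical_grid(), scale * v)
}

#' Synthetic dose-response dataset from a known pigment
#'
#' Generates the heterologous action-spectroscopy design: narrowband
#' stimuli at the stated wavelengths, each presented over a range of total
#' photon fluxes, with noise-free responses on a 5-parameter log-logistic
#' curve of the true pigment's effective flux (univariance) and optional
#' multiplicative Gaussian noise.
#'
#' @param lambda_max True pigment peak (nm).
#' @param wavelengths Stimulus wavelengths (nm); default the six-wavelength
#'   design 435-525 nm.
#' @param log_flux Total photon flux levels, log10 photons cm^-2 s^-1.
#' @param ll5_params Named vector `b, c, d, e, f` of the generating curve;
#'   `e` is in effective-flux units.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   response noise (0 = noise-free).
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @return A dose-response tibble: `stimulus_id`, `wavelength_nm`,
#'   `log10_photon_flux`, `response`, with the truth recorded in
#'   attributes `lambda_max` and `ll5_params`.
#' @export
synth_dose_response <- function(lambda_max,
                                wavelengths = c(435, 460, 470, 490, 500, 525),
                                log_flux = seq(11, 16, length.out = 6),
                                ll5_params = c(b = -1, c = 0, d = 1, e = 10^13.5, f = 1),
                                noise_cv = 0,
                                seed = NULL) {
  if (noise_cv > 0 && is.null(seed)) {
    abort("supply `seed` when `noise_cv > 0`.")
  }
  data <- tidyr::expand_grid(
    wavelength_nm = wavelengths,
    log10_photon_flux = log_flux
  )
  data$stimulus_id <- sprintf("nb%03d", data$wavelength_nm)
  data <- effective_photon_flux(data, lambda_max)
  p <- ll5_params
  resp <- ll5(data$effective_flux, p["b"], p["c"], p["d"], p["e"], p["f"])
  if (noise_cv > 0) {
    set.seed(seed)
    resp <- resp * (1 + rnorm(length(resp), sd = noise_cv))
  }
  out <- dplyr::select(
    dplyr::mutate(data, response = resp),
    "stimulus_id", "wavelength_nm", "log10_photon_flux", "response"
  )
  attr(out, "lambda_max") <- lambda_max
  attr(out, "ll5_params") <- ll5_params
  out
}

#' Synthetic sensor count log
#'
#' Simulates 10-channel sensor readings for a list of SPDs: per-channel
#' counts proportional to the responsivity-weighted irradiance integral,
#' multiplied by an automatically chosen gain (largest power-of-two gain
#' in 8-512 that keeps raw counts within a 16-bit range) and the
#' integration time, with optional Poisson-like shot noise.
#'
#' @param spds Named list of `spd` objects (names become `stimulus_id`).
#' @param responsivities Channel responsivity table
#'   ([default_channel_responsivities()]).
#' @param integration_ms Integration time (ms).
#' @param counts_per_unit Raw counts per (W m^-2 aggregated in-band) per
#'   ms at unit gain; the default device sensitivity is chosen so that
#'   normalized counts remain at or above 1 (no floor truncation) over the
#'   irradiance range of the calibration study, mirroring the count
#'   scaling convention of the protocol this simulates.
#' @param noise Add Poisson-like noise (sd = sqrt(count))?
#' @param seed Integer seed (required when `noise = TRUE`).
#' @return A sensor log tibble: `stimulus_id`, `gain`, `integration_ms`,
#'   channel columns.
#' @export
synth_sensor_log <- function(spds,
                             responsivities = default_channel_responsivities(),
                             integration_ms = 182,
                             counts_per_unit = 100,
                             noise = FALSE,
                             seed = NULL) {
  if (noise && is.null(seed)) {
    abort("supply `seed` when `noise = TRUE`.")
  }
  if (is.null(names(spds)) || any(names(spds) == "")) {
    abort("`spds` must be a fully named list.")
  }
  if (noise) {
    set.seed(seed)
  }
  gains <- 2^(3:9)
  purrr::imap_dfr(spds, function(s, sid) {
    s <- resample_to_canonical(as_spd(s))
    base <- vapply(
      sensor_channels,
      function(ch) sum(s$irradiance * responsivities[[ch]]),
      numeric(1)
    )
    per_gain_unit <- max(base) * counts_per_unit * integration_ms
    ok <- gains[per_gain_unit * gains <= 65535]
    gain <- if (length(ok) > 0) max(ok) else gains[1]
    raw <- base * counts_per_unit * integration_ms * gain
    if (noise) {
      raw <- pmax(raw + rnorm(length(raw), sd = sqrt(raw)), 0)
    }
    tibble::as_tibble(c(
      list(stimulus_id = sid, gain = gain, integration_ms = integration_ms),
      setNames(as.list(raw), sensor_channels)
    ))
  })
}

#' Synthetic daylight series over solar angle
#'
#' A stand-in for field daylight measurements: D65-shaped spectra with a
#' mild blue tilt at low solar angles, scaled so that photopic illuminance
#' follows a smooth twilight-to-day curve (log-linear through twilight,
#' saturating near 1e5 lux at high sun), with optional small seeded
#' day-to-day scatter.
#'
#' @param angles Solar angles in degrees, within -6 to 60.
#' @param species,receptor Target for the returned angle-to-EDI map.
#' @param registry Optional registry.
#' @param jitter_sd Log10 scatter added to the illuminance curve (0 for a
#'   deterministic series).
#' @param seed Integer seed (required when `jitter_sd > 0`).
#' @return A list with `spds` (named list of `spd`, one per angle) and
#'   `map` (tibble `solar_angle_deg`, `edi_lux` for the requested target).
#' @export
synth_daylight_series <- function(angles = seq(-6, 60, by = 2),
                                  species = "Human",
                                  receptor = "melanopsin",
                                  registry = NULL,
                                  jitter_sd = 0,
                                  seed = NULL) {
  if (any(angles < -6 | angles > 60)) {
    abort("`angles` must lie within [-6, 60] degrees.")
  }
  if (jitter_sd > 0 && is.null(seed)) {
    abort("supply `seed` when `jitter_sd > 0`.")
  }
  if (jitter_sd > 0) {
    set.seed(seed)
  }
  profile <- lookup_profile(species, registry)
  if (!receptor %in% names(profile$sensitivities)) {
    abort(sprintf("receptor '%s' absent for species '%s'.", receptor, species))
  }
  base <- d65_spd()
  grid <- canonical_grid()
  spds <- lapply(angles, function(a) {
    tilt <- 0.25 * (1 - plogis((a - 5) / 5)) # bluer sky through twilight
    shape <- base$irradiance * (560 / grid)^tilt
    s <- new_spd(grid, shape / max(shape))
    log_lux <- 5 * plogis((a - 1) / 4.5) +
      if (jitter_sd > 0) rnorm(1, sd = jitter_sd) else 0
    scale_to_illuminance(s, 10^log_lux)
  })
  names(spds) <- sprintf("angle_%+05.1f", angles)
  edis <- vapply(spds, function(s) {
    row <- edi(s, profile)
    row$edi_lux[row$receptor == receptor]
  }, numeric(1))
  list(
    spds = spds,
    map = tibble::tibble(solar_angle_deg = angles, edi_lux = unname(edis))
  )
}
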