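# Multichannel light-sensor calibration: mapping 10-channel count logs to
# species-specific alpha-opic EDIs.
#
# Model: log10(EDI) ~ sum_i w_i * log10(working counts_i), weights
# unconstrained in sign, fitted by least squares on a calibration set of
# known (counts, EDI) pairs extrapolated to a fixed grid of EDI levels.

sensor_channels <- c(
  "ch415", "ch445", "ch480", "ch515", "ch555",
  "ch590", "ch630", "ch680", "ch910", "clear"
)

channel_peaks <- c(415, 445, 480, 515, 555, 590, 630, 680, 910)

#' Synthetic channel responsivity model
#'
#' Gaussian responsivities (default FWHM 30 nm) at the nine narrowband
#' channel peaks of the AS7341-class sensor plus a flat clear channel over
#' 350-900 nm. Each narrowband channel additionally carries a small flat
#' stray-light (out-of-band leakage) term: interference-filter channels
#' reject out-of-band light imperfectly, and that leakage is what keeps
#' every channel responsive to every stimulus -- a property the
#' log-domain calibration model relies on (a channel reading exactly zero
#' is floored and carries no intensity information). This is a fixture
#' convention for simulation and testing, not a characterization of any
#' real part.
#'
#' @param fwhm Full width at half maximum of the narrowband channels (nm).
#' @param stray Relative out-of-band responsivity of the narrowband
#'   channels (default 5e-4, i.e. roughly -33 dB rejection).
#' @return A tibble with `wavelength_nm` and one column per channel.
#' @export
default_channel_responsivities <- function(fwhm = 30, stray = 5e-4) {
  grid <- canonical_grid()
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  window <- as.numeric(grid >= 350 & grid <= 900)
  out <- tibble::tibble(wavelength_nm = as.numeric(grid))
  for (i in seq_along(channel_peaks)) {
    out[[sensor_channels[i]]] <-
      exp(-(grid - channel_peaks[i])^2 / (2 * sigma^2)) + stray * window
  }
  out$clear <- window
  out
}

#' Normalize raw sensor counts to working counts
#'
#' Working counts are raw counts divided by (gain x integration time),
#' scaled by 1e6 and floored at 1, so that log10 working counts are always
#' defined and non-negative.
#'
#' @param counts A sensor log tibble: `stimulus_id`, `gain`,
#'   `integration_ms`, and the ten channel columns `ch415` ... `ch910`,
#'   `clear`.
#' @return The tibble with channel columns replaced by working counts and
#'   the `gain`/`integration_ms` columns dropped.
#' @export
normalize_counts <- function(counts) {
  need <- c("gain", "integration_ms", sensor_channels)
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L) {
    abort(sprintf("`counts` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(counts$gain <= 0) || any(counts$integration_ms <= 0)) {
    abort("`gain` and `integration_ms` must be positive.")
  }
  out <- counts
  for (ch in sensor_channels) {
    out[[ch]] <- pmax(counts[[ch]] / (counts$gain * counts$integration_ms) * 1e6, 1)
  }
  dplyr::select(out, -dplyr::all_of(c("gain", "integration_ms")))
}

#' Expand anchor measurements to a fixed EDI calibration grid
#'
#' For each distinct spectrum, scales the working counts of its anchor
#' measurement(s) linearly (pre-floor) to a consistent set of target EDI
#' levels, exploiting sensor linearity. Multiple anchors per spectrum are
#' averaged after scaling.
#'
#' @param working Working-count tibble from [normalize_counts()] with a
#'   `stimulus_id` column identifying the spectrum.
#' @param edis Tibble pairing each row of `working` with its measured EDI:
#'   columns `stimulus_id` and `edi_lux` (> 0), in row order matching
#'   `working`.
#' @param grid Target EDI levels in log10 lux (default -1, 0.5, 2).
#' @return A tibble with `stimulus_id`, `log_edi`, and scaled (re-floored)
#'   working counts, one row per spectrum x grid level.
#' @export
extrapolate_calibration_grid <- function(working, edis, grid = c(-1, 0.5, 2)) {
  if (nrow(working) != nrow(edis)) {
    abort("`working` and `edis` must have the same number of rows.")
  }
  if (any(edis$edi_lux <= 0)) {
    abort("anchor EDIs must be positive.")
  }
  cmat <- as.matrix(working[, sensor_channels])
  purrr::map_dfr(unique(working$stimulus_id), function(sid) {
    rows <- which(working$stimulus_id == sid)
    purrr::map_dfr(grid, function(g) {
      scaled <- vapply(rows, function(r) {
        cmat[r, ] * 10^(g - log10(edis$edi_lux[r]))
      }, numeric(length(sensor_channels)))
      avg <- pmax(rowMeans(scaled), 1)
      tibble::as_tibble(c(
        list(stimulus_id = sid, log_edi = g),
        setNames(as.list(avg), sensor_channels)
      ))
    })
  })
}

#' Fit channel weights for one target quantity
#'
#' Least-squares weights w such that `sum_i w_i log10(counts_i)` best
#' reproduces `log10(EDI)` over the calibration set. The model is linear
#' in the weights, so the normal-equation solution is the exact minimum;
#' channels with no usable signal (log counts identically zero, e.g. a
#' dark 910-nm channel) are rank-deficient and get weight 0.
#'
#' @param calibration Tibble from [extrapolate_calibration_grid()]:
#'   `stimulus_id`, `log_edi`, channel columns.
#' @param species,receptor Labels recorded in the calibration entry.
#' @return A `sensor_calibration_entry`: named weight vector, training
#'   RMSE (log10 units), row count, EDI grid range.
#' @export
fit_channel_weights <- function(calibration, species = NA_character_,
                                receptor = NA_character_) {
  n_spec <- length(unique(calibration$stimulus_id))
  if (nrow(calibration) < length(sensor_channels) || n_spec < 2L) {
    abort(sprintf(
      "underdetermined calibration: %d rows / %d spectra for %d channels.",
      nrow(calibration), n_spec, length(sensor_channels)
    ))
  }
  x <- log10(as.matrix(calibration[, sensor_channels]))
  y <- calibration$log_edi
  fit <- lm.fit(x, y)
  w <- fit$coefficients
  w[is.na(w)] <- 0
  pred <- drop(x %*% w)
  structure(
    list(
      weights = setNames(w, sensor_channels),
      species = species,
      receptor = receptor,
      training_rmse = sqrt(mean((pred - y)^2)),
      n_rows = nrow(calibration),
      log_edi_range = range(y)
    ),
    class = "sensor_calibration_entry"
  )
}

#' Calibrate a sensor for all photoreceptor classes of a species
#'
#' Convenience wrapper: extrapolates the anchor measurements to the EDI
#' grid separately for every photoreceptor class of the species and fits
#' one weight vector per class.
#'
#' @param working Working counts ([normalize_counts()]) of the anchor
#'   readings, with `stimulus_id`.
#' @param edi_table Tibble of measured EDIs for the anchor readings: one
#'   row per (reading, receptor), columns `stimulus_id`, `receptor`,
#'   `edi_lux`, in reading order within each receptor.
#' @param species Species label.
#' @param grid EDI grid in log10 lux.
#' @return A `sensor_calibration`: named list of entries keyed by receptor.
#' @export
calibrate_sensor <- function(working, edi_table, species = NA_character_,
                             grid = c(-1, 0.5, 2)) {
  entries <- lapply(split(edi_table, edi_table$receptor), function(ed) {
    calib <- extrapolate_calibration_grid(
      working, ed[, c("stimulus_id", "edi_lux")],
      grid = grid
    )
    fit_channel_weights(calib, species = species, receptor = ed$receptor[1])
  })
  structure(
    list(species = species, entries = entries, grid = grid),
    class = "sensor_calibration"
  )
}

#' Predict EDI from sensor counts
#'
#' \eqn{\widehat{EDI} = 10^{\sum_i w_i \log_{10} C_i}} with the fitted
#' channel weights and working counts \eqn{C_i}. Strictly positive by
#' construction. Warns when a prediction falls outside the EDI range the
#' calibration was fitted on (extrapolation).
#'
#' @param calibration A `sensor_calibration_entry` (or a
#'   `sensor_calibration` together with `receptor`).
#' @param counts Working-count tibble (from [normalize_counts()]), or a raw
#'   log that still has `gain`/`integration_ms` columns (normalized
#'   automatically).
#' @param receptor Receptor key when `calibration` is a full
#'   `sensor_calibration`.
#' @return Numeric vector of predicted EDIs (lux), one per row of `counts`.
#' @export
predict_edi <- function(calibration, counts, receptor = NULL) {
  if (inherits(calibration, "sensor_calibration")) {
    if (is.null(receptor) || !receptor %in% names(calibration$entries)) {
      abort(sprintf(
        "no calibration entry for receptor '%s'; available: %s.",
        receptor %||% "<missing>",
        paste(names(calibration$entries), collapse = ", ")
      ))
    }
    calibration <- calibration$entries[[receptor]]
  }
  if (!inherits(calibration, "sensor_calibration_entry")) {
    abort("`calibration` must be a sensor calibration (entry).")
  }
  if (all(c("gain", "integration_ms") %in% names(counts))) {
    counts <- normalize_counts(counts)
  }
  x <- log10(as.matrix(counts[, sensor_channels]))
  pred_log <- drop(x %*% calibration$weights)
  rng <- calibration$log_edi_range
  if (any(pred_log < rng[1] - 0.5 | pred_log > rng[2] + 0.5)) {
    warn("some predictions extrapolate beyond the calibration EDI grid.")
  }
  10^pred_log
}

#' Log absolute error between predicted and measured EDI
#'
#' @param predicted,measured Positive EDI values (lux).
#' @return `|log10(predicted) - log10(measured)|`, elementwise.
#' @examples
#' log_abs_error(2, 1) # 0.301
#' @export
log_abs_error <- function(predicted, measured) {
  if (any(predicted <= 0) || any(measured <= 0)) {
    abort("`predicted` and `measured` must be strictly positive.")
  }
  abs(log10(predicted) - log10(measured))
}

#' @export
tidy.sensor_calibration_entry <- function(x, ...) {
  tibble::tibble(
    species = x$species, receptor = x$receptor,
    channel = names(x$weights), weight = unname(x$weights)
  )
}

#' @export
tidy.sensor_calibration <- function(x, ...) {
  purrr::map_dfr(x$entries, tidy)
}

#' @export
glance.sensor_calibration_entry <- function(x, ...) {
  tibble::tibble(
    species = x$species, receptor = x$receptor,
    training_rmse = x$training_rmse, n_rows = x$n_rows,
    sum_weights = sum(x$weights)
  )
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf(
    "<sensor_calibration> %s: %s\n", x$species,
    paste(names(x$entries), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a sensor calibration as JSON
#'
#' @param calibration A `sensor_calibration`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the restored `sensor_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "sensor_calibration"))
  payload <- list(
    format = "alphaopix-sensor-calibration",
    version = 1L,
    species = calibration$species,
    grid = calibration$grid,
    entries = lapply(calibration$entries, function(e) {
      list(
        receptor = e$receptor,
        weights = as.list(e$weights),
        training_rmse = e$training_rmse,
        n_rows = e$n_rows,
        log_edi_range = e$log_edi_range
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "alphaopix-sensor-calibration")) {
    abort("not an alphaopix sensor calibration file.")
  }
  entries <- lapply(names(payload$entries), function(r) {
    e <- payload$entries[[r]]
    structure(
      list(
        weights = setNames(unlist(e$weights), names(e$weights)),
        species = payload$species,
        receptor = e$receptor,
        training_rmse = e$training_rmse,
        n_rows = e$n_rows,
        log_edi_range = unlist(e$log_edi_range)
      ),
      class = "sensor_calibration_entry"
    )
  })
  names(entries) <- names(payload$entries)
  structure(
    list(
      species = payload$species,
      entries = entries,
      grid = unlist(payload$grid)
    ),
    class = "sensor_calibration"
  )
}

#' Calibration spectra set for the sensor study
#'
#' The thirteen-spectrum calibration design: ten narrowband Gaussian
#' stimuli spanning the visible range plus the three parametric broadband
#' whites, all as unit-scale SPDs.
#'
#' @param narrowband_peaks Peak wavelengths (nm) of the narrowband set.
#' @param hwhm_nm Narrowband half width at half maximum (nm).
#' @return Named list of `spd` objects.
#' @export
calibration_spectra <- function(narrowband_peaks = c(
                                  405, 435, 460, 470, 490,
                                  500, 525, 550, 595, 635
                                ),
                                hwhm_nm = 7) {
  nb <- lapply(narrowband_peaks, gaussian_spd, hwhm_nm = hwhm_nm)
  names(nb) <- sprintf("nb%03d", narrowband_peaks)
  bb <- lapply(c("led", "fluorescent", "rgb_mix"), broadband_white)
  names(bb) <- c("led", "fluorescent", "rgb_mix")
  c(nb, bb)
}

#' Synthetic end-to-end sensor accuracy study
#'
#' Simulates the full dosimeter calibration/validation protocol for one
#' species with the synthetic Gaussian channel model: anchor readings of
#' each calibration spectrum at three irradiances, extrapolation to the
#' fixed EDI grid, per-receptor weight fitting, then held-out validation
#' readings of the same spectra across a wide irradiance range, scored as
#' log absolute error between predicted and spectroradiometric EDI.
#'
#' @param species Species name or profile.
#' @param seed Integer seed for the simulated shot noise.
#' @param spectra Calibration spectra ([calibration_spectra()]).
#' @param anchor_irradiance Total irradiances (W m^-2, 1-nm sum) of the
#'   three anchor readings per spectrum.
#' @param validation_irradiance Total irradiances of the held-out
#'   readings per spectrum.
#' @param registry Optional registry.
#' @param grid Calibration EDI grid, log10 lux.
#' @return A list with `calibration` (the fitted `sensor_calibration`),
#'   `errors` (tibble `receptor`, `stimulus_id`, `irradiance_W_m2`,
#'   `edi_true`, `edi_pred`, `log_abs_error`) and `summary` (tibble
#'   `receptor`, `median_log_abs_error`, `max_log_abs_error`).
#' @export
sensor_error_study <- function(species,
                               seed,
                               spectra = calibration_spectra(),
                               anchor_irradiance = c(0.1, 1, 10),
                               validation_irradiance = 10^seq(
                                 log10(0.2), log10(80),
                                 length.out = 10
                               ),
                               registry = NULL,
                               grid = c(-1, 0.5, 2)) {
  profile <- lookup_profile(species, registry)
  scale_set <- function(irradiances) {
    out <- list()
    for (sid in names(spectra)) {
      s <- spectra[[sid]]
      total <- sum(s$irradiance)
      for (irr in irradiances) {
        out[[sprintf("%s@%g", sid, irr)]] <- new_spd(
          s$wavelength_nm, s$irradiance * irr / total
        )
      }
    }
    out
  }
  true_edis <- function(spds) {
    purrr::imap_dfr(spds, function(s, key) {
      res <- edi(s, profile)
      res$stimulus_id <- sub("@.*$", "", key)
      res$irradiance_W_m2 <- sum(s$irradiance)
      res
    })
  }

  cal_spds <- scale_set(anchor_irradiance)
  cal_log <- synth_sensor_log(cal_spds, noise = TRUE, seed = seed)
  cal_log$stimulus_id <- sub("@.*$", "", names(cal_spds))
  cal_working <- normalize_counts(cal_log)
  cal_edi <- true_edis(cal_spds)
  calib <- calibrate_sensor(
    cal_working,
    dplyr::select(cal_edi, "stimulus_id", "receptor", edi_lux = "edi_lux"),
    species = profile$species_name, grid = grid
  )

  val_spds <- scale_set(validation_irradiance)
  val_log <- synth_sensor_log(val_spds, noise = TRUE, seed = seed + 1)
  val_log$stimulus_id <- sub("@.*$", "", names(val_spds))
  val_working <- normalize_counts(val_log)
  val_edi <- true_edis(val_spds)

  errors <- purrr::map_dfr(names(calib$entries), function(rc) {
    pred <- suppressWarnings(predict_edi(calib, val_working, receptor = rc))
    truth <- val_edi$edi_lux[val_edi$receptor == rc]
    tibble::tibble(
      receptor = rc,
      stimulus_id = val_working$stimulus_id,
      irradiance_W_m2 = rep(validation_irradiance, times = length(spectra)),
      edi_true = truth,
      edi_pred = pred,
      log_abs_error = log_abs_error(pred, truth)
    )
  })
  summary <- errors |>
    dplyr::group_by(.data$receptor) |>
    dplyr::summarise(
      median_log_abs_error = median(.data$log_abs_error),
      max_log_abs_error = max(.data$log_abs_error),
      .groups = "drop"
    )
  list(calibration = calib, errors = errors, summary = summary)
}
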