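# Irradiance-response curve analysis: re-express stimulus intensities in
# candidate light metrics, fit 4-parameter log-logistic curves, and rank
# metrics by variance explained. Also maps EDIs to equivalent solar angles.

#' Re-express stimulus intensities in a chosen light metric
#'
#' Reconstructs each narrowband stimulus as a Gaussian SPD from its peak
#' wavelength and half width at half maximum, scales it to the stated
#' total irradiance, and converts to the requested metric: photopic lux,
#' a species/receptor alpha-opic EDI, or raw total irradiance (identity).
#'
#' @param data IRC tibble: columns `peak_nm`, `hwhm_nm`,
#'   `irradiance_W_m2` (total, i.e. the 1-nm sum of the SPD), `response`,
#'   optionally `response_sem`.
#' @param metric `"photopic_lux"`, `"edi"` or `"irradiance"`.
#' @param species,receptor Species (name or profile) and photoreceptor
#'   class, required for `metric = "edi"`.
#' @param registry Optional registry for species lookup.
#' @return `data` with added columns `intensity` (in the chosen metric)
#'   and `zero_sensitivity` (flag: the stimulus is invisible to the
#'   metric).
#' @export
reexpress_intensity <- function(data,
                                metric = c("edi", "photopic_lux", "irradiance"),
                                species = NULL, receptor = NULL,
                                registry = NULL) {
  metric <- match.arg(metric)
  if (metric == "irradiance") {
    return(dplyr::mutate(data,
      intensity = .data$irradiance_W_m2,
      zero_sensitivity = FALSE
    ))
  }
  stimuli <- dplyr::distinct(data, .data$peak_nm, .data$hwhm_nm)
  # conversion factor per unit total irradiance, per unique stimulus shape
  stimuli$factor <- vapply(seq_len(nrow(stimuli)), function(i) {
    s <- gaussian_spd(stimuli$peak_nm[i], stimuli$hwhm_nm[i], scale = 1)
    total <- sum(s$irradiance)
    if (metric == "photopic_lux") {
      photopic_illuminance(s) / total
    } else {
      profile <- lookup_profile(species, registry)
      if (is.null(receptor) || !receptor %in% names(profile$sensitivities)) {
        abort(sprintf(
          "metric receptor '%s' absent for species '%s'; available: %s.",
          receptor %||% "<missing>", profile$species_name,
          paste(names(profile$sensitivities), collapse = ", ")
        ))
      }
      row <- edi(s, profile)
      row$edi_lux[row$receptor == receptor] / total
    }
  }, numeric(1))
  out <- dplyr::left_join(data, stimuli, by = c("peak_nm", "hwhm_nm"))
  dplyr::mutate(out,
    intensity = .data$irradiance_W_m2 * .data$factor,
    zero_sensitivity = .data$intensity == 0,
    factor = NULL
  )
}

#' Fit a 4-parameter log-logistic irradiance-response curve
#'
#' Least-squares fit of \eqn{c + (d - c)/(1 + \exp(b(\ln x - \ln e)))}
#' with optional 1/SEM^2 weighting. R-squared is computed against the
#' total sum of squares about the mean response and reported as computed
#' (it can be negative for a metric that orders the data badly).
#'
#' @param data Data frame with intensity and response columns.
#' @param intensity,response Column names holding positive intensities and
#'   responses. Observations with non-positive intensity are dropped with
#'   a message.
#' @param weight_by_sem Use `response_sem` for 1/SEM^2 weighting?
#' @param metric_label Optional label stored with the fit.
#' @return An `irc4_fit`: coefficients `b, c, d, e`, `r_squared`, `rss`,
#'   `nobs`, `metric`.
#' @export
fit_irc4 <- function(data, intensity = "intensity", response = "response",
                     weight_by_sem = FALSE, metric_label = NA_character_) {
  x <- data[[intensity]]
  y <- data[[response]]
  wts <- if (weight_by_sem && "response_sem" %in% names(data)) {
    1 / data$response_sem^2
  } else {
    rep(1, length(y))
  }
  keep <- is.finite(x) & x > 0 & is.finite(y)
  if (any(!keep)) {
    inform(sprintf("dropping %d observation(s) with non-positive intensity.", sum(!keep)))
  }
  x <- x[keep]
  y <- y[keep]
  wts <- wts[keep]
  if (length(x) < 5L) {
    abort("need at least 5 observations with positive intensity.")
  }
  if (diff(range(y)) == 0) {
    abort("degenerate data: responses are constant.")
  }
  lx <- log(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c + (d - c) / (1 + exp(b * (lx - le))),
      start = list(b = -1, c = min(y), d = max(y), le = median(lx)),
      weights = wts,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    abort("4-parameter fit failed to converge.")
  }
  cf <- coef(fit)
  pred <- fitted(fit)
  rss <- sum(wts * (y - pred)^2)
  tss <- sum(wts * (y - sum(wts * y) / sum(wts))^2)
  structure(
    list(
      coefficients = c(
        b = unname(cf["b"]), c = unname(cf["c"]),
        d = unname(cf["d"]), e = exp(unname(cf["le"]))
      ),
      r_squared = 1 - rss / tss,
      rss = rss,
      nobs = length(y),
      metric = metric_label,
      dose = x,
      response = y,
      fitted = pred
    ),
    class = "irc4_fit"
  )
}

#' @export
tidy.irc4_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.irc4_fit <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, r_squared = x$r_squared, rss = x$rss, nobs = x$nobs
  )
}

#' @export
print.irc4_fit <- function(x, ...) {
  cat(sprintf(
    "<irc4_fit>%s R^2 = %.3f (n = %d)\n",
    if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
    x$r_squared, x$nobs
  ))
  invisible(x)
}

#' @export
autoplot.irc4_fit <- function(object, ...) {
  df <- tibble::tibble(
    intensity = object$dose, response = object$response,
    fitted = object$fitted
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$intensity, .data$response)) +
    ggplot2::geom_point(...) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = object$metric %||% "Intensity", y = "Response",
      subtitle = sprintf("R^2 = %.3f", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Compare candidate light metrics by IRC goodness of fit
#'
#' Re-expresses the same irradiance-response observations in each candidate
#' metric, fits one 4-parameter curve per metric, and returns the metrics
#' ranked by R-squared.
#'
#' @param data IRC tibble (see [reexpress_intensity()]); needs at least 2
#'   distinct stimulus spectra.
#' @param metrics Named list of metric specs. Each element is either the
#'   string `"photopic_lux"` / `"irradiance"`, or a
#'   `list(species =, receptor =)` for an alpha-opic EDI.
#' @param exclude_below_nm Optionally drop stimuli with `peak_nm` below
#'   this value before fitting (e.g. 400 to exclude UV stimuli).
#' @param registry Optional registry for species lookup.
#' @return A tibble `metric`, `r_squared`, `nobs`, sorted by decreasing
#'   R-squared, with the fit objects in a `fit` list-column.
#' @export
compare_metrics <- function(data, metrics, exclude_below_nm = NULL,
                            registry = NULL) {
  if (length(metrics) < 2L) {
    abort("supply at least 2 metrics to compare.")
  }
  if (length(unique(paste(data$peak_nm, data$hwhm_nm))) < 2L) {
    abort("metric comparison needs at least 2 distinct stimulus spectra.")
  }
  if (!is.null(exclude_below_nm)) {
    data <- dplyr::filter(data, .data$peak_nm >= exclude_below_nm)
  }
  fits <- purrr::imap(metrics, function(m, label) {
    re <- if (is.character(m)) {
      reexpress_intensity(data, metric = m)
    } else {
      reexpress_intensity(data,
        metric = "edi", species = m$species,
        receptor = m$receptor, registry = registry
      )
    }
    suppressMessages(fit_irc4(re, metric_label = label))
  })
  tibble::tibble(
    metric = names(fits),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    nobs = vapply(fits, `[[`, numeric(1), "nobs"),
    fit = unname(fits)
  ) |>
    dplyr::arrange(dplyr::desc(.data$r_squared))
}

#' Solar angle equivalent to an EDI
#'
#' Interpolates a monotone (solar angle, EDI) lookup table, linearly in
#' angle versus log10 EDI (the relationship is approximately log-linear
#' through twilight).
#'
#' @param map Tibble with columns `solar_angle_deg` and `edi_lux`, EDI
#'   strictly increasing with angle, at least 5 rows.
#' @param edi_lux EDI value(s) within the table's range.
#' @return Solar angle(s) in degrees.
#' @export
solar_angle_for_edi <- function(map, edi_lux) {
  if (nrow(map) < 5L) {
    abort("`map` needs at least 5 rows.")
  }
  map <- dplyr::arrange(map, .data$solar_angle_deg)
  if (any(diff(map$edi_lux) <= 0)) {
    abort("`map` EDI must increase strictly with solar angle.")
  }
  rng <- range(map$edi_lux)
  if (any(edi_lux < rng[1] | edi_lux > rng[2])) {
    abort(sprintf(
      "EDI out of range; the map covers %.3g to %.3g lux.", rng[1], rng[2]
    ))
  }
  approx(log10(map$edi_lux), map$solar_angle_deg, xout = log10(edi_lux))$y
}
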