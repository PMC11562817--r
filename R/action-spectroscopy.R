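# Heterologous action spectroscopy: estimating a pigment's lambda_max from
# multi-wavelength dose-response data.
#
# Inner loop for a candidate lambda_max: re-weight each stimulus' photon
# flux by the Govardovskii template (univariance), fit a 5-parameter
# log-logistic dose-response model to (effective flux, response), take the
# residual sum of squares. The outer loop minimises that RSS over
# lambda_max (coarse 5-nm grid scan bracketed Brent refinement), and a
# bootstrap over observations gives the estimate and its error.

#' Effective photon flux under a candidate pigment
#'
#' Re-expresses each stimulus' total photon flux as the flux effectively
#' seen by a pigment with the given peak wavelength: total flux times the
#' quantal Govardovskii template weight at the stimulus wavelength, or the
#' template-weighted sum of the photon flux spectrum when a full stimulus
#' SPD is supplied in an `spd` list-column.
#'
#' @param data Dose-response tibble with columns `wavelength_nm` and
#'   `log10_photon_flux` (photons cm^-2 s^-1), optionally an `spd`
#'   list-column of stimulus spectra.
#' @param lambda_max Candidate pigment peak (nm).
#' @return `data` with an added `effective_flux` column (linear photons
#'   cm^-2 s^-1).
#' @export
effective_photon_flux <- function(data, lambda_max) {
  flux <- 10^data$log10_photon_flux
  if ("spd" %in% names(data)) {
    peak_w <- max(govardovskii_eval(canonical_grid(), lambda_max))
    eff <- vapply(seq_along(flux), function(i) {
      s <- resample_to_canonical(as_spd(data$spd[[i]]))
      pf <- energy_to_photon_flux(s)$photon_flux
      if (sum(pf) == 0) {
        return(0)
      }
      rel <- pf / sum(pf) # relative photon spectrum; total is given per row
      w <- govardovskii_eval(s$wavelength_nm, lambda_max) / peak_w
      flux[i] * sum(rel * w)
    }, numeric(1))
  } else {
    w <- govardovskii_eval(data$wavelength_nm, lambda_max)
    peak_w <- max(govardovskii_eval(canonical_grid(), lambda_max))
    eff <- flux * w / peak_w
  }
  dplyr::mutate(data, effective_flux = eff)
}

ll5_curve <- function(x, b, c, d, le, f) {
  c + (d - c) / (1 + exp(b * (log(x) - le)))^f
}

#' Fit a 5-parameter log-logistic dose-response model
#'
#' Least-squares fit of
#' \eqn{f(x) = c + (d - c) / (1 + \exp(b(\ln x - \ln e)))^f}
#' to response versus (effective) flux, via Levenberg-Marquardt. Starting
#' values: `c` = min response, `d` = max response, `e` = median flux,
#' `b = -1` (rising curve), `f = 1`.
#'
#' @param data Data frame with the dose and response columns.
#' @param dose,response Column names (tidy-eval) holding the dose (linear
#'   flux, > 0) and response amplitude. Defaults `effective_flux` and
#'   `response`.
#' @return An `ll5_fit` object: coefficients `b, c, d, e, f`, `rss`,
#'   `converged`, fitted values. A fit that fails to converge is returned
#'   with `rss = Inf` so an outer optimizer can reject the candidate.
#' @examples
#' x <- 10^seq(11, 16, length.out = 30)
#' y <- ll5(x, b = -1, c = 0, d = 1, e = 1e13, f = 1)
#' fit_ll5(tibble::tibble(effective_flux = x, response = y))
#' @export
fit_ll5 <- function(data, dose = "effective_flux", response = "response",
                    start = NULL) {
  x <- data[[dose]]
  y <- data[[response]]
  keep <- is.finite(x) & x > 0 & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 6L) {
    abort("need at least 6 observations with positive dose.")
  }
  if (diff(range(log10(x))) < 1) {
    abort("doses must span at least 1 log10 unit.")
  }
  if (diff(range(y)) == 0) {
    abort("degenerate data: responses are constant.")
  }
  lx <- log(x)
  fit <- ll5_fit_engine(lx, y, start = start)
  if (is.null(fit)) {
    out <- list(
      coefficients = c(b = NA, c = NA, d = NA, e = NA, f = NA),
      rss = Inf, converged = FALSE, fitted = rep(NA_real_, length(y)),
      dose = x, response = y
    )
    class(out) <- "ll5_fit"
    return(out)
  }
  out <- c(fit, list(dose = x, response = y))
  class(out) <- "ll5_fit"
  out
}

# Levenberg-Marquardt LL5 fit with the linear parameters (c, d) profiled
# out: for fixed (b, ln e, ln f) the gate g = (1 + exp(b(lx - le)))^-f
# enters linearly, y ~ c (1 - g) + d g, so c and d are solved exactly per
# evaluation and only 3 parameters are iterated.
ll5_fit_engine <- function(lx, y, start = NULL) {
  ybar <- mean(y)
  gate <- function(p) {
    1 / (1 + exp(pmin(p[1] * (lx - p[2]), 700)))^exp(p[3])
  }
  # exact least-squares (c, d) for a fixed gate, via 2x2 normal equations
  profile_cd <- function(g) {
    h <- 1 - g
    s1 <- sum(h * h)
    s2 <- sum(h * g)
    s3 <- sum(g * g)
    det <- s1 * s3 - s2 * s2
    if (!is.finite(det) || det < 1e-12 * (s1 + s3 + 1e-300)^2) {
      return(c(ybar, ybar)) # flat gate: constant fit
    }
    t1 <- sum(y * h)
    t2 <- sum(y * g)
    c((t1 * s3 - t2 * s2) / det, (s1 * t2 - s2 * t1) / det)
  }
  resid_fun <- function(p) {
    g <- gate(p)
    cd <- profile_cd(g)
    y - (cd[1] * (1 - g) + cd[2] * g)
  }
  p0 <- if (is.null(start)) c(-1, median(lx), 0) else unlist(start)[1:3]
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 150)
    ),
    error = function(e) NULL
  )
  if (is.null(lm_fit)) {
    return(NULL)
  }
  p <- lm_fit$par
  g <- gate(p)
  cd <- profile_cd(g)
  fitted <- cd[1] * (1 - g) + cd[2] * g
  list(
    coefficients = c(
      b = p[1], c = unname(cd[1]), d = unname(cd[2]),
      e = exp(p[2]), f = exp(p[3])
    ),
    rss = sum((y - fitted)^2),
    converged = lm_fit$info %in% 1:4,
    fitted = fitted,
    raw_coef = p
  )
}

#' Evaluate the 5-parameter log-logistic curve
#'
#' @param x Dose (linear scale, > 0).
#' @param b,c,d,e,f Curve parameters: slope, lower asymptote, upper
#'   asymptote, inflection dose, asymmetry.
#' @return Response values.
#' @export
ll5 <- function(x, b, c, d, e, f = 1) {
  ll5_curve(x, b, c, d, log(e), f)
}

#' @export
tidy.ll5_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @export
glance.ll5_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, converged = x$converged, nobs = length(x$response)
  )
}

#' @export
print.ll5_fit <- function(x, ...) {
  cat("<ll5_fit>", if (!x$converged) "(not converged)", "\n")
  print(round(x$coefficients, 4))
  cat("RSS:", format(x$rss), "\n")
  invisible(x)
}

# RSS of the best LL5 fit for one candidate lambda_max
lambda_rss <- function(data, lambda_max) {
  make_lambda_rss(data)(lambda_max)
}

# Precompute per-dataset quantities once, returning a fast RSS(lambda)
# closure for the grid scan and Brent refinement.
make_lambda_rss <- function(data) {
  flux <- 10^data$log10_photon_flux
  y <- data$response
  has_spd <- "spd" %in% names(data)
  if (has_spd) {
    rel <- lapply(data$spd, function(s) {
      s <- resample_to_canonical(as_spd(s))
      pf <- energy_to_photon_flux(s)$photon_flux
      if (sum(pf) == 0) rep(0, length(pf)) else pf / sum(pf)
    })
  } else {
    wl <- data$wavelength_nm
  }
  grid <- canonical_grid()
  function(lambda_max) {
    tw <- govardovskii_eval(grid, lambda_max)
    peak_w <- max(tw)
    eff <- if (has_spd) {
      flux * vapply(rel, function(r) sum(r * tw), numeric(1)) / peak_w
    } else {
      flux * govardovskii_eval(wl, lambda_max) / peak_w
    }
    keep <- is.finite(eff) & eff > 0 & is.finite(y)
    # large-but-finite sentinel: optimize() dislikes Inf objectives
    if (sum(keep) < 6L ||
      diff(range(log10(eff[keep]))) < 1 ||
      diff(range(y[keep])) == 0) {
      return(.rss_unfit)
    }
    fit <- ll5_fit_engine(log(eff[keep]), y[keep])
    if (is.null(fit) || !fit$converged) .rss_unfit else fit$rss
  }
}

.rss_unfit <- 1e300

optimize_lambda <- function(data, range, grid_step) {
  rss_fun <- make_lambda_rss(data)
  grid <- seq(range[1], range[2], by = grid_step)
  rss <- vapply(grid, rss_fun, numeric(1))
  if (all(rss >= .rss_unfit)) {
    abort("no candidate lambda_max produced a convergent dose-response fit.")
  }
  best <- which.min(rss)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- optimize(rss_fun, interval = c(lo, hi), tol = 0.02)
  # guard: keep the grid winner if Brent landed on a worse local dip
  if (opt$objective <= rss[best]) opt$minimum else grid[best]
}

#' Estimate pigment lambda_max from dose-response data
#'
#' Searches, within 400-600 nm, for the pigment peak wavelength whose
#' template-weighted effective fluxes best collapse the responses onto a
#' single 5-parameter log-logistic curve (minimum residual sum of squares).
#' The search is a 5-nm grid scan followed by Brent refinement in the best
#' bracket. Uncertainty comes from bootstrapping: the optimization is
#' repeated on n-out-of-n resamples of the observations (with replacement)
#' and the mean and standard deviation of the replicate estimates are
#' reported.
#'
#' @param data Dose-response tibble: columns `wavelength_nm` (or an `spd`
#'   list-column), `log10_photon_flux`, `response`, optionally
#'   `stimulus_id`.
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param range Search range in nm.
#' @param grid_step Coarse pre-scan step in nm.
#' @param chromophore Isoform the data were collected with (`"11-cis"` or
#'   `"9-cis"`).
#' @param correct_to_11cis If `TRUE` and `chromophore = "9-cis"`, add the
#'   16-nm isoform correction to all reported values.
#' @return A `lambda_max_estimate`: `lambda_max` (bootstrap mean), `sd`,
#'   `point_estimate` (full-data optimum), `replicates`, `n_bootstrap`,
#'   `chromophore`.
#' @export
estimate_lambda_max <- function(data,
                                n_bootstrap = 1000,
                                seed = NULL,
                                range = c(400, 600),
                                grid_step = 5,
                                chromophore = c("11-cis", "9-cis"),
                                correct_to_11cis = FALSE) {
  chromophore <- match.arg(chromophore)
  n_spectra <- if ("spd" %in% names(data)) {
    length(unique(data$stimulus_id %||% seq_len(nrow(data))))
  } else {
    length(unique(data$wavelength_nm))
  }
  if (n_spectra < 2L) {
    abort(paste(
      "lambda_max is unidentifiable from a single stimulus spectrum;",
      "provide at least 2 spectrally distinct stimuli."
    ))
  }
  point <- optimize_lambda(data, range, grid_step)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n <- nrow(data)
  reps <- vapply(seq_len(n_bootstrap), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(
      optimize_lambda(data[idx, , drop = FALSE], range, grid_step),
      error = function(e) NA_real_
    )
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  shift <- 0
  out_chromophore <- chromophore
  if (correct_to_11cis) {
    corrected <- apply_chromophore_shift(0, chromophore)
    shift <- as.numeric(corrected)
    out_chromophore <- attr(corrected, "chromophore")
  }
  structure(
    list(
      lambda_max = mean(reps) + shift,
      sd = sd(reps),
      point_estimate = point + shift,
      replicates = reps + shift,
      n_bootstrap = n_bootstrap,
      chromophore = out_chromophore
    ),
    class = "lambda_max_estimate"
  )
}

#' @export
tidy.lambda_max_estimate <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates), lambda_max = x$replicates)
}

#' @export
glance.lambda_max_estimate <- function(x, ...) {
  tibble::tibble(
    lambda_max = x$lambda_max,
    sd = x$sd,
    point_estimate = x$point_estimate,
    n_bootstrap = x$n_bootstrap,
    chromophore = x$chromophore
  )
}

#' @export
print.lambda_max_estimate <- function(x, ...) {
  cat(sprintf(
    "<lambda_max_estimate> %.1f +/- %.1f nm (%s, %d bootstrap replicates)\n",
    x$lambda_max, x$sd, x$chromophore, x$n_bootstrap
  ))
  invisible(x)
}

#' @export
autoplot.lambda_max_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$lambda_max)) +
    ggplot2::geom_histogram(bins = 30, ...) +
    ggplot2::geom_vline(xintercept = object$lambda_max, linetype = 2) +
    ggplot2::labs(
      x = expression(lambda[max] ~ (nm)),
      y = "Bootstrap replicates"
    ) +
    ggplot2::theme_minimal()
}

#' Response amplitude from a luminescence time course
#'
#' Amplitude of a stimulus-evoked transient: the maximum (or the
#' integral) of the response window after subtracting the mean baseline.
#'
#' @param timecourse Data frame with columns `time_s` and `luminescence`.
#' @param baseline_window Two-element window (s) of pre-stimulus baseline.
#' @param response_window Two-element window (s) of the response; must
#'   start at or after the baseline ends.
#' @param mode `"max"` (default) or `"integral"` (trapezoidal area of the
#'   baseline-subtracted response).
#' @return Amplitude (arbitrary units, or units * s for `"integral"`).
#' @export
extract_response_amplitude <- function(timecourse,
                                       baseline_window = c(0, 10),
                                       response_window = c(10, 30),
                                       mode = c("max", "integral")) {
  mode <- match.arg(mode)
  if (response_window[1] < baseline_window[2]) {
    abort("response window must start at or after the baseline window ends.")
  }
  t <- timecourse$time_s
  y <- timecourse$luminescence
  base <- y[t >= baseline_window[1] & t <= baseline_window[2]]
  resp_idx <- t >= response_window[1] & t <= response_window[2]
  if (length(base) == 0L || !any(resp_idx)) {
    abort("baseline or response window contains no samples.")
  }
  y0 <- mean(base)
  ty <- t[resp_idx]
  ry <- y[resp_idx] - y0
  if (mode == "max") {
    max(ry)
  } else {
    sum(diff(ty) * (head(ry, -1) + tail(ry, -1)) / 2)
  }
}
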