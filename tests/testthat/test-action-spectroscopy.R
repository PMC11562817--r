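test_that("effective photon flux weights total flux by the template", {
  sens <- govardovskii_template(481)
  peak <- sens$wavelength_nm[which.max(sens$weight)]
  d <- tibble::tibble(
    wavelength_nm = c(peak, 435, 460, 470, 490, 500, 525),
    log10_photon_flux = rep(14, 7)
  )
  out <- effective_photon_flux(d, 481)
  # at the numerical peak the weight is (numerically) 1
  expect_equal(out$effective_flux[1], 1e14, tolerance = 1e-6)
  # remaining stimuli match the independent template transcription
  oracle_w <- oracle_pigment_template(d$wavelength_nm[-1], 481) /
    max(oracle_pigment_template(canonical_grid(), 481))
  expect_equal(out$effective_flux[-1], 1e14 * oracle_w, tolerance = 1e-9)
})

test_that("effective flux supports full stimulus spectra via univariance", {
  d <- tibble::tibble(
    stimulus_id = c("a", "b"),
    log10_photon_flux = c(14, 14),
    spd = list(gaussian_spd(480, 5), gaussian_spd(520, 5))
  )
  out <- effective_photon_flux(d, 480)
  expect_gt(out$effective_flux[1], out$effective_flux[2])
  expect_lt(out$effective_flux[1], 1e14) # band-averaged weight < 1
})

test_that("LL5 fitting recovers noise-free parameters essentially exactly", {
  x <- 10^seq(11, 16, length.out = 36)
  truth <- c(b = -1.3, c = 0.08, d = 1.5, e = 10^13.2, f = 1.6)
  y <- ll5(x, truth["b"], truth["c"], truth["d"], truth["e"], truth["f"])
  fit <- fit_ll5(tibble::tibble(effective_flux = x, response = y))
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-10 * sum(y^2))
  expect_equal(unname(fit$coefficients["d"]), 1.5, tolerance = 1e-4)
})

test_that("LL5 fitting rejects degenerate input", {
  x <- 10^seq(11, 16, length.out = 12)
  expect_error(
    fit_ll5(tibble::tibble(effective_flux = x, response = rep(2, 12))),
    "constant"
  )
  expect_error(
    fit_ll5(tibble::tibble(effective_flux = x[1:4], response = rnorm(4))),
    "at least 6"
  )
  expect_error(
    fit_ll5(tibble::tibble(
      effective_flux = seq(1e13, 1.1e13, length.out = 10),
      response = runif(10)
    )),
    "1 log"
  )
})

test_that("with symmetric data the LL5 asymmetry reduces to 1", {
  x <- 10^seq(11, 16, length.out = 36)
  y <- ll5(x, -1, 0, 1, 10^13.5, 1)
  fit <- fit_ll5(tibble::tibble(effective_flux = x, response = y))
  expect_equal(unname(fit$coefficients["f"]), 1, tolerance = 1e-3)
})

test_that("noise-free estimation recovers the true peak within 1 nm of the grid oracle", {
  d <- synth_dose_response(490)
  point <- alphaopix:::optimize_lambda(d, c(400, 600), 5)
  expect_lt(abs(point - 490), 1)
  rss_fun <- alphaopix:::make_lambda_rss(d)
  grid <- seq(485, 495, 1)
  oracle <- grid[which.min(vapply(grid, rss_fun, numeric(1)))]
  expect_lt(abs(point - oracle), 1)
})

test_that("bootstrap estimates are reproducible and seed-stable", {
  d <- synth_dose_response(480, noise_cv = 0.05, seed = 21)
  e1 <- estimate_lambda_max(d, n_bootstrap = 30, seed = 7)
  e2 <- estimate_lambda_max(d, n_bootstrap = 30, seed = 7)
  expect_identical(e1$replicates, e2$replicates)
  e3 <- estimate_lambda_max(d, n_bootstrap = 30, seed = 8)
  expect_lt(abs(e1$lambda_max - e3$lambda_max), 2 * (e1$sd + e3$sd))
})

test_that("adding a constant to all responses leaves the lambda estimate unchanged", {
  d <- synth_dose_response(470)
  shifted <- dplyr::mutate(d, response = response + 5)
  p1 <- alphaopix:::optimize_lambda(d, c(400, 600), 5)
  p2 <- alphaopix:::optimize_lambda(shifted, c(400, 600), 5)
  expect_equal(p1, p2, tolerance = 0.05)
})

test_that("single-spectrum data are rejected as unidentifiable", {
  d <- tibble::tibble(
    stimulus_id = "only",
    wavelength_nm = 480,
    log10_photon_flux = seq(11, 16, length.out = 12),
    response = ll5(10^seq(11, 16, length.out = 12), -1, 0, 1, 1e13)
  )
  expect_error(estimate_lambda_max(d, n_bootstrap = 5), "unidentifiable")
})

test_that("the 9-cis correction can be applied to the estimate", {
  d <- synth_dose_response(465)
  est <- estimate_lambda_max(d,
    n_bootstrap = 10, seed = 3,
    chromophore = "9-cis", correct_to_11cis = TRUE
  )
  expect_equal(est$lambda_max, 481, tolerance = 1)
  expect_identical(est$chromophore, "11-cis")
})

test_that("response amplitude extraction handles max and integral modes", {
  t <- seq(0, 60, by = 2)
  flat <- tibble::tibble(time_s = t, luminescence = rep(100, length(t)))
  expect_equal(extract_response_amplitude(flat), 0)

  stepped <- tibble::tibble(
    time_s = t,
    luminescence = ifelse(t >= 12 & t <= 20, 300, 100)
  )
  expect_equal(extract_response_amplitude(stepped), 200)

  # alpha-function transient: amplitude t*exp(1 - t/tau)/tau peaks at tau
  tau <- 4
  tt <- seq(0, 40, by = 0.05)
  resp <- ifelse(tt > 10, (tt - 10) / tau * exp(1 - (tt - 10) / tau), 0)
  tc <- tibble::tibble(time_s = tt, luminescence = 50 + resp)
  got <- extract_response_amplitude(tc,
    baseline_window = c(0, 10),
    response_window = c(10, 40), mode = "integral"
  )
  expect_equal(got, tau * exp(1), tolerance = 0.02)

  expect_error(
    extract_response_amplitude(flat,
      baseline_window = c(0, 10),
      response_window = c(5, 20)
    ),
    "after the baseline"
  )
})
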