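make_counts <- function(values, gain = 8, t = 182) {
  tibble::as_tibble(c(
    list(stimulus_id = "x", gain = gain, integration_ms = t),
    setNames(as.list(values), alphaopix:::sensor_channels)
  ))
}

test_that("count normalization floors at 1 and removes gain/integration effects", {
  zeros <- normalize_counts(make_counts(rep(0, 10)))
  expect_true(all(as.matrix(zeros[, alphaopix:::sensor_channels]) == 1))

  a <- normalize_counts(make_counts(rep(512, 10), gain = 512))
  b <- normalize_counts(make_counts(rep(8, 10), gain = 8))
  expect_equal(
    as.matrix(a[, alphaopix:::sensor_channels]),
    as.matrix(b[, alphaopix:::sensor_channels])
  )

  c1 <- normalize_counts(make_counts(rep(100, 10), gain = 8))
  c2 <- normalize_counts(make_counts(rep(200, 10), gain = 16))
  expect_equal(
    as.matrix(c1[, alphaopix:::sensor_channels]),
    as.matrix(c2[, alphaopix:::sensor_channels])
  )
  expect_error(normalize_counts(make_counts(rep(1, 10), gain = 0)), "positive")
})

test_that("grid extrapolation scales counts linearly from anchors", {
  working <- normalize_counts(make_counts(rep(1820, 10))) # working = 1.25e6... scaled
  working$stimulus_id <- "s1"
  edis <- tibble::tibble(stimulus_id = "s1", edi_lux = 10) # 1 log lux anchor
  grid <- extrapolate_calibration_grid(working, edis, grid = c(1, 2))
  w <- as.matrix(working[, alphaopix:::sensor_channels])
  g1 <- as.matrix(grid[grid$log_edi == 1, alphaopix:::sensor_channels])
  g2 <- as.matrix(grid[grid$log_edi == 2, alphaopix:::sensor_channels])
  expect_equal(as.numeric(g1), as.numeric(w)) # anchor already on a level
  expect_equal(as.numeric(g2), as.numeric(w) * 10)
  expect_error(
    extrapolate_calibration_grid(working, tibble::tibble(stimulus_id = "s1", edi_lux = 0)),
    "positive"
  )
})

test_that("noisy anchors extrapolate close to noise-free grid counts", {
  spds <- list(a = gaussian_spd(480, 10, 0.2), b = broadband_white("led", 0.1))
  clean <- synth_sensor_log(spds)
  noisy <- synth_sensor_log(spds, noise = TRUE, seed = 2)
  edis <- tibble::tibble(stimulus_id = c("a", "b"), edi_lux = c(5, 8))
  gc <- extrapolate_calibration_grid(normalize_counts(clean), edis)
  gn <- extrapolate_calibration_grid(normalize_counts(noisy), edis)
  mc <- as.matrix(gc[, alphaopix:::sensor_channels])
  mn <- as.matrix(gn[, alphaopix:::sensor_channels])
  big <- mc > 0.1 * max(mc) # compare where shot noise is small
  expect_lt(max(abs(mn[big] / mc[big] - 1)), 0.02)
})

test_that("an exactly proportional channel yields an exact single-channel calibration", {
  # counts on ch480 proportional to EDI, all others dark (floored)
  log_edi <- rep(c(-1, 0.5, 2), times = 4)
  sid <- rep(c("s1", "s2", "s3", "s4"), each = 3)
  counts <- matrix(1, nrow = 12, ncol = 10,
    dimnames = list(NULL, alphaopix:::sensor_channels)
  )
  counts[, "ch480"] <- 10^log_edi # exactly proportional, unit factor
  calib <- tibble::as_tibble(cbind(
    tibble::tibble(stimulus_id = sid, log_edi = log_edi),
    tibble::as_tibble(counts)
  ))
  fit <- fit_channel_weights(calib, species = "Test", receptor = "melanopsin")
  expect_lt(fit$training_rmse, 1e-8)
  pred <- predict_edi(fit, calib[, c(alphaopix:::sensor_channels)])
  expect_equal(log10(pred), log_edi, tolerance = 1e-6)
})

test_that("calibration is invariant to row order and refuses underdetermined input", {
  spds <- calibration_spectra()[1:6]
  log <- synth_sensor_log(spds)
  working <- normalize_counts(log)
  working$stimulus_id <- names(spds)
  edis <- tibble::tibble(stimulus_id = names(spds), edi_lux = c(2, 10, 30, 60, 90, 5))
  g <- extrapolate_calibration_grid(working, edis)
  f1 <- fit_channel_weights(g)
  f2 <- fit_channel_weights(g[sample(nrow(g)), ])
  expect_equal(f1$weights, f2$weights, tolerance = 1e-8)
  expect_error(fit_channel_weights(g[1:6, ]), "underdetermined")
})

test_that("prediction with unit counts returns 1 lux and errors without a calibration entry", {
  spds <- calibration_spectra()[1:4]
  log <- synth_sensor_log(spds)
  working <- normalize_counts(log)
  working$stimulus_id <- names(spds)
  edis <- tidyr::expand_grid(
    receptor = "melanopsin",
    tibble::tibble(stimulus_id = names(spds), edi_lux = c(2, 10, 40, 80))
  )
  calib <- calibrate_sensor(working, edis, species = "Test")
  ones <- make_counts(rep(1, 10))
  ones_working <- ones
  ones_working$gain <- NULL
  ones_working$integration_ms <- NULL
  for (ch in alphaopix:::sensor_channels) ones_working[[ch]] <- 1
  pred <- suppressWarnings(predict_edi(calib, ones_working, receptor = "melanopsin"))
  expect_equal(pred, 1)
  expect_error(predict_edi(calib, ones_working, receptor = "l_cone"), "no calibration entry")
})

test_that("log absolute error behaves as a log-scale distance", {
  expect_equal(log_abs_error(5, 5), 0)
  expect_equal(log_abs_error(2, 1), 0.301, tolerance = 1e-3)
  expect_equal(log_abs_error(1, 10), 1)
  expect_error(log_abs_error(0, 1), "positive")
})

test_that("calibrations survive a JSON round trip", {
  spds <- calibration_spectra()[1:4]
  log <- synth_sensor_log(spds)
  working <- normalize_counts(log)
  working$stimulus_id <- names(spds)
  edis <- tidyr::expand_grid(
    receptor = c("melanopsin", "rod"),
    tibble::tibble(stimulus_id = names(spds), edi_lux = c(2, 10, 40, 80))
  )
  calib <- calibrate_sensor(working, edis, species = "Test")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(calib, path)
  back <- read_calibration(path)
  expect_equal(back$species, calib$species)
  expect_equal(
    back$entries$melanopsin$weights,
    calib$entries$melanopsin$weights,
    tolerance = 1e-12
  )
})

test_that("predicted EDI scales log-linearly with the light within the calibrated range", {
  st <- sensor_error_study("Cat", seed = 31)
  e <- st$calibration$entries$melanopsin
  expect_equal(sum(e$weights), 1, tolerance = 0.1)
})
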