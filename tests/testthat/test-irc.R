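# shared synthetic IRC dataset: responses generated as a 4PL of the true
# mouse melanopic EDI across 8 narrowband stimuli
make_irc_data <- function() {
  stimuli <- tibble::tibble(
    peak_nm = c(365, 405, 435, 470, 500, 525, 560, 595), hwhm_nm = 10
  )
  data <- tidyr::expand_grid(
    stimuli,
    irradiance_W_m2 = 10^seq(-4, 1, length.out = 6)
  )
  truth <- reexpress_intensity(data,
    metric = "edi",
    species = "Mouse", receptor = "melanopsin"
  )
  data$response <- ll5(pmax(truth$intensity, 1e-300), b = -1, c = 0, d = 3, e = 1)
  data
}

test_that("intensity re-expression converts through the alpha-opic pipeline", {
  d <- tibble::tibble(
    peak_nm = c(480, 365), hwhm_nm = 10,
    irradiance_W_m2 = 0.1, response = c(1, 1)
  )
  mouse_mel <- reexpress_intensity(d,
    metric = "edi", species = "Mouse",
    receptor = "melanopsin"
  )
  expect_true(all(mouse_mel$intensity > 0))

  ident <- reexpress_intensity(d, metric = "irradiance")
  expect_equal(ident$intensity, d$irradiance_W_m2)

  # lens divergence: same UV dose, human melanopic EDI orders of magnitude lower
  human_mel <- reexpress_intensity(d,
    metric = "edi", species = "Human",
    receptor = "melanopsin"
  )
  # more than an order of magnitude with the packaged lens models
  ratio <- mouse_mel$intensity[2] / human_mel$intensity[2]
  expect_gt(ratio, 10)

  expect_error(
    reexpress_intensity(d, metric = "edi", species = "Mouse", receptor = "l_cone"),
    "absent"
  )
})

test_that("noise-free 4PL data are fitted with R^2 of 1", {
  x <- 10^seq(-1, 3, length.out = 24)
  y <- ll5(x, -1.2, 0.2, 2.5, 20)
  fit <- fit_irc4(tibble::tibble(intensity = x, response = y))
  expect_gt(fit$r_squared, 1 - 1e-6)
})

test_that("shuffled responses give near-zero R^2", {
  set.seed(17)
  x <- 10^seq(-1, 3, length.out = 40)
  y <- sample(ll5(x, -1, 0, 2, 20))
  fit <- fit_irc4(tibble::tibble(intensity = x, response = y))
  expect_lt(fit$r_squared, 0.3)
})

test_that("single-spectrum data fit but refuse metric comparison", {
  d <- tibble::tibble(
    peak_nm = 480, hwhm_nm = 10,
    irradiance_W_m2 = 10^seq(-3, 1, length.out = 8)
  )
  d$response <- ll5(d$irradiance_W_m2, -1, 0, 1, 0.01)
  re <- reexpress_intensity(d, metric = "irradiance")
  expect_s3_class(fit_irc4(re), "irc4_fit")
  expect_error(
    compare_metrics(d, metrics = list(
      a = "photopic_lux", b = "irradiance"
    )),
    "distinct stimulus spectra"
  )
})

test_that("the generating metric dominates the R^2 ranking", {
  data <- make_irc_data()
  res <- compare_metrics(data, metrics = list(
    mouse_melanopic = list(species = "Mouse", receptor = "melanopsin"),
    human_melanopic = list(species = "Human", receptor = "melanopsin"),
    photopic_lux = "photopic_lux"
  ))
  r <- setNames(res$r_squared, res$metric)
  expect_gt(r["mouse_melanopic"], r["photopic_lux"])
  expect_gte(r["mouse_melanopic"], max(r))
})

test_that("dropping UV stimuli improves the human melanopic fit", {
  data <- make_irc_data()
  full <- compare_metrics(data, metrics = list(
    human_melanopic = list(species = "Human", receptor = "melanopsin"),
    photopic_lux = "photopic_lux"
  ))
  nouv <- compare_metrics(data,
    metrics = list(
      human_melanopic = list(species = "Human", receptor = "melanopsin"),
      photopic_lux = "photopic_lux"
    ),
    exclude_below_nm = 400
  )
  expect_gt(
    nouv$r_squared[nouv$metric == "human_melanopic"],
    full$r_squared[full$metric == "human_melanopic"]
  )
})

test_that("R^2 is invariant to rescaling a metric (the e parameter absorbs scale)", {
  x <- 10^seq(-1, 3, length.out = 24)
  y <- ll5(x, -1, 0.1, 2, 20) + 0.01 * sin(seq_along(x))
  f1 <- fit_irc4(tibble::tibble(intensity = x, response = y))
  f2 <- fit_irc4(tibble::tibble(intensity = x * 137, response = y))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-6)
})

test_that("solar-angle lookup interpolates a monotone map in log EDI", {
  angles <- seq(-6, 20, by = 2)
  map <- tibble::tibble(
    solar_angle_deg = angles,
    edi_lux = 10^(0.25 * angles + 1) # exactly log-linear
  )
  # exact rows return themselves
  expect_equal(solar_angle_for_edi(map, map$edi_lux[4]), angles[4])
  # midpoints of a log-linear map interpolate with < 0.1 degree error
  mid_angles <- angles[-1] - 1
  got <- solar_angle_for_edi(map, 10^(0.25 * mid_angles + 1))
  expect_lt(max(abs(got - mid_angles)), 0.1)
  # monotone output
  edis <- 10^seq(0, 5, length.out = 11)
  expect_true(all(diff(solar_angle_for_edi(map, edis)) > 0))
  expect_error(solar_angle_for_edi(map, 1e9), "out of range")
})
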