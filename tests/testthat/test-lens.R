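test_that("absorbance converts to percent transmission by 100 * 10^-A", {
  expect_equal(absorbance_to_transmission(0), 100)
  expect_equal(absorbance_to_transmission(1), 10)
  expect_equal(absorbance_to_transmission(0.301), 50, tolerance = 0.1 / 50)
  expect_error(absorbance_to_transmission(NA), "finite")
})

test_that("harmonization reproduces an exact logistic within 0.01 and stays in [0, 1]", {
  raw <- logistic_lens_raw(n = 30)
  lens <- harmonize_transmission(raw)
  truth <- plogis((lens$wavelength_nm - 420) / 15)
  truth <- truth / max(plogis((raw$wavelength_nm - 420) / 15))
  inside <- lens$wavelength_nm >= 350 & lens$wavelength_nm <= 700
  expect_lt(max(abs(lens$transmission[inside] - truth[inside])), 0.01)
  expect_equal(max(lens$transmission), 1)
  expect_true(all(lens$transmission >= 0 & lens$transmission <= 1))
  # long side held at the last value
  expect_equal(
    lens$transmission[lens$wavelength_nm == 800],
    lens$transmission[lens$wavelength_nm == 700]
  )
})

test_that("harmonization normalizes sub-unity maxima and clamps the short-side extension", {
  raw <- logistic_lens_raw(n = 30)
  raw$transmission <- raw$transmission * 0.95
  lens <- harmonize_transmission(raw)
  expect_equal(max(lens$transmission), 1)

  # steep curve whose first-3-point slope crosses zero before 310 nm
  steep <- logistic_lens_raw(n = 20, lambda50 = 450, width = 5, lo = 420, hi = 600)
  lens2 <- harmonize_transmission(steep)
  expect_true(all(lens2$transmission[lens2$wavelength_nm < 400] == 0))
})

test_that("harmonization uses smoothing splines for dense noisy data", {
  set.seed(42)
  wl <- seq(350, 720, length.out = 80)
  noisy <- tibble::tibble(
    wavelength_nm = wl,
    transmission = plogis((wl - 420) / 15) + rnorm(80, sd = 0.02)
  )
  lens <- harmonize_transmission(noisy)
  truth <- plogis((lens$wavelength_nm - 420) / 15)
  inside <- lens$wavelength_nm >= 360 & lens$wavelength_nm <= 710
  expect_lt(max(abs(lens$transmission[inside] - truth[inside])), 0.05)
})

test_that("harmonization rejects sparse or narrow input", {
  expect_error(
    harmonize_transmission(tibble::tibble(
      wavelength_nm = c(400, 450, 500), transmission = c(0, 0.5, 1)
    )),
    "at least 4"
  )
  expect_error(
    harmonize_transmission(tibble::tibble(
      wavelength_nm = seq(400, 450, 10), transmission = runif(6)
    )),
    "100 nm"
  )
})

test_that("averaging lens sources is identity-safe and interpolates lambda50", {
  l1 <- parametric_lens(380, 10)
  one <- average_sources(list(l1))
  expect_equal(one$transmission, l1$transmission)
  expect_identical(attr(one, "source_count"), 1L)

  two_same <- average_sources(list(l1, l1))
  expect_equal(two_same$transmission, l1$transmission)

  l2 <- parametric_lens(420, 10)
  avg <- average_sources(list(l1, l2))
  expect_gt(lens_lambda50(avg), 380)
  expect_lt(lens_lambda50(avg), 420)
  expect_error(average_sources(list()), "at least one")
})

test_that("lens filtering multiplies pointwise and respects the filtered flag", {
  clear <- alphaopix:::new_lens(rep(1, 501))
  mel <- govardovskii_template(480)
  same <- in_vivo_sensitivity(mel, clear)
  expect_equal(same$weight, mel$weight)
  expect_true(attr(same, "filtered"))
  expect_error(in_vivo_sensitivity(same, clear), "twice")

  # a blocking lens can only ever attenuate (before renormalization)
  lens <- parametric_lens(440, 12)
  prod <- mel$weight * lens$transmission
  expect_true(all(prod <= mel$weight + 1e-12))
})

test_that("strong short-wavelength blocking red-shifts a UV pigment but barely moves an L-like one", {
  lens <- parametric_lens(440, 12)
  uv <- in_vivo_sensitivity(govardovskii_template(360), lens)
  expect_gt(uv$wavelength_nm[which.max(uv$weight)], 360 + 10)

  lws <- in_vivo_sensitivity(govardovskii_template(560), lens)
  expect_lt(abs(lws$wavelength_nm[which.max(lws$weight)] - 560), 3)
})

test_that("parametric lens hits its midpoint and limits", {
  l <- parametric_lens(400, 10)
  # logistic midpoint before the (tiny) max-normalization
  expect_equal(l$transmission[l$wavelength_nm == 400], 0.5, tolerance = 1e-3)
  expect_equal(lens_lambda50(l), 400, tolerance = 0.1)

  steep <- parametric_lens(400, 1e-6)
  expect_lt(steep$transmission[steep$wavelength_nm == 399], 1e-6)
  expect_equal(steep$transmission[steep$wavelength_nm == 401], 1)

  mole <- parametric_lens(310, 10)
  expect_true(all(mole$transmission[mole$wavelength_nm >= 350] > 0.97))
  expect_error(parametric_lens(305, 10), "310")
})
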