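# Shared fixtures built in code.

# a smooth broadband SPD for linearity/property checks
random_spd <- function(seed) {
  set.seed(seed)
  grid <- alphaopix::canonical_grid()
  centers <- runif(4, 350, 750)
  amps <- runif(4, 0.1, 1)
  widths <- runif(4, 20, 120)
  v <- rowSums(vapply(
    seq_along(centers),
    function(i) amps[i] * exp(-(grid - centers[i])^2 / (2 * widths[i]^2)),
    numeric(length(grid))
  ))
  alphaopix::spd(grid, v)
}

# logistic lens raw data sampled at n points
logistic_lens_raw <- function(n = 30, lambda50 = 420, width = 15,
                              lo = 350, hi = 700) {
  wl <- seq(lo, hi, length.out = n)
  tibble::tibble(
    wavelength_nm = wl,
    transmission = plogis((wl - lambda50) / width)
  )
}

# independent direct transcription of the A1 pigment nomogram, used as an
# oracle against the package's evaluator (kept deliberately separate from
# the implementation)
oracle_pigment_template <- function(wavelength_nm, lambda_max) {
  x <- lambda_max / wavelength_nm
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  A <- 69.7
  B <- 28
  b <- 0.922
  C <- -14.9
  cc <- 1.104
  D <- 0.674
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelength_nm - lmb) / bb)^2)
  alpha + beta
}
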