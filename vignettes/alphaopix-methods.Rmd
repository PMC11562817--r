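---
title: "Species-specific α-opic light metrology: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-specific α-opic light metrology: models, conventions and limits}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaopix)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, the numerical
conventions, and what the synthetic data generators do and do not tell
you about real data.

## The measurement model

A photoreceptor does not see "light"; it sees photons weighted by its own
spectral sensitivity. The α-opic system therefore replaces the single
photopic weighting V(λ) with one weighting function per photoreceptor
class per species, and reports three linked quantities: the α-opic
irradiance (the weighted energy integral, W·m⁻²), the α-opic efficacy of
standard daylight (K^D65, W·lm⁻¹), and the equivalent daylight
illuminance (EDI = irradiance / K^D65, lux). EDI anchors every
photoreceptor in every species to the same physical reference — an amount
of D65 daylight — which is what makes cross-species statements such as
"this lamp gives a mouse the melanopsin drive of civil twilight"
well-posed.

Two structural identities follow from the definitions, and the test suite
asserts both. First, D65 scaled to X photopic lux has EDI = X for every
photoreceptor of every species — the efficacy constant is defined to make
this so. Second, EDI is invariant to any positive rescaling of the
sensitivity function, because the scale cancels between the efficacy and
the irradiance. The practical consequence is that EDIs are robust to the
(arbitrary) unit-peak normalization of sensitivities, whereas raw α-opic
irradiances are not.

## Building in-vivo sensitivities

Sensitivities are built in three steps.

**Pigment template.** The A1 visual-pigment nomogram of Govardovskii and
colleagues gives the full absorbance spectrum of an opsin pigment from a
single parameter, its peak wavelength λmax: an α-band parameterised in
λmax/λ plus a Gaussian β-band whose position and amplitude scale with
λmax. The template constants are compiled into the package; the accepted
validity envelope here is λmax ∈ [330, 620] nm, covering the registry's
range (358–567 nm) with margin. The template is a *quantal* sensitivity
(probability of capturing a photon).

**Energy flavor.** The irradiance integral weights *energy*, so the
quantal template is converted by multiplying by λ and re-normalizing:
at equal energy, longer wavelengths deliver proportionally more photons.
The conversion shifts the peak a few nm to longer wavelengths (e.g. a
480-nm quantal pigment peaks near 483 nm in energy units, and near 490 nm
once lens filtering is added — consistent with the conventional human
melanopic function peaking near 490 nm for a 480-nm pigment). The package
keeps quantal weighting available (`flavor = "quantal"` in
`species_registry()`) because some published sensitivity tables are
quantal; the default is energy, for dimensional consistency of the
irradiance integral.

**Pre-receptoral filtering.** The dominant spectral filter in front of
mammalian photoreceptors is the lens, and lens transmission alone is an
adequate approximation of whole-eye filtering for these purposes. In-vivo
sensitivity is the pointwise product of the template and the lens curve,
re-normalized to unit peak. Species differ enormously here: small rodents
with UV-sensitive S-cones have lenses transmitting far into the UV
(half-transmission wavelength λ50 near 340–360 nm), while primate and
ungulate lenses block below ~400–425 nm. This divergence — not pigment
differences — is why human melanopic EDI misrepresents mouse responses to
UV-containing light.

The bundled registry stores per-species pigment peaks and a parametric
logistic lens per species. The lens curves are labelled synthetic
stand-ins: published digitized lens data are not redistributed with the
package, so each species carries a logistic model whose λ50 was chosen to
reflect its published lens class (UV-transmissive for mouse, rat, gerbil,
striped mouse, degu and hamster; UV-blocking for the larger mammals, with
the human reference lens at λ50 = 420 nm). Users with real harmonized
curves can build profiles from them directly with `species_profile()`.
Human registry peaks are the standard-observer in-vivo α-opic values used
as template inputs; the D65/EDI identity holds by construction regardless,
but human absolute sensitivities are an approximation of the official
tabulated functions, not a reproduction.

## Lens harmonization rules

Published lens transmissions arrive as scans, tables, or relative
absorbances at heterogeneous wavelength supports. `harmonize_transmission()`
applies a fixed pipeline, in order: absorbance is converted by
T = 100·10^(−A) where needed; fewer than 50 raw points are interpolated
with cubic splines, 50 or more with a cubic smoothing spline on 50 knots
(knots equally spaced in wavelength — the smoothing degree beyond the knot
count is this package's choice); the curve is normalized to unit maximum
*before* the extensions so they inherit the normalized scale; the long
side is held at its last value out to 800 nm; the short side is extended
to the grid edge along the slope of the first three interpolated values;
negatives are clipped to 0 and values above 1 to 1. The short-side slope
uses interpolated (not raw) points, and the extension continues below
310 nm to the 300-nm grid edge under the same clipping. λ50 is the
shortest wavelength at which the curve first reaches 0.5, linearly
interpolated between grid points.

## Numerical conventions

All spectra live on a canonical 1-nm grid over 300–800 nm; integrals are
rectangular sums with Δλ = 1 nm (matching the 1-nm harmonization
convention and CIE tabular practice — the integration rule is this
package's choice, and at 1 nm the difference from trapezoidal quadrature
is negligible for smooth spectra). Inputs off the grid are linearly
interpolated; wavelengths outside the supplied support are zero, never
extrapolated, so no energy is invented in the UV where species differ
most. V(λ) (CIE 1924, 5-nm table) and the D65 relative spectrum (5-nm
table) are bundled and spline-interpolated to the grid; every quantity
that uses D65 is a ratio in which its absolute scale cancels, and
V(555) = 1 exactly. Energy/photon conversion uses λ/(hc) with CODATA
constants; K_m = 683 lm/W.

## Estimating λmax from action spectroscopy

Heterologous action spectroscopy measures a cell-based response to a set
of narrowband stimuli over a range of intensities. Under univariance, a
pigment with peak λmax sees stimulus *i* at total photon flux Φᵢ as
*effective* flux wᵢ(λmax)·Φᵢ, with wᵢ the quantal template weight. The
estimator therefore iterates: propose λmax → recompute effective fluxes →
fit a single 5-parameter log-logistic curve
c + (d−c)/(1+exp(b(ln x − ln e)))^f to all (effective flux, response)
pairs → score by residual sum of squares. The λmax minimising that RSS is
found by a 5-nm grid scan over 400–600 nm followed by Brent refinement in
the best bracket; the pre-scan guards against local minima that a bare
Brent search over the full interval could fall into. Uncertainty comes
from n-out-of-n bootstrap resampling of observations (default 1000
replicates; the replicate mean and SD are the estimate and its error).

The inner fit profiles the two linear parameters (c, d) out of the
log-logistic, leaving a 3-parameter Levenberg–Marquardt problem in
(b, ln e, ln f); starting values are b = −1, e at the median effective
flux, f = 1, with c and d solved exactly at every step. A fit that fails
to converge returns an effectively infinite RSS so the outer search
simply avoids that λmax. Identifiability requires at least two spectrally
distinct stimuli; single-wavelength data are refused because the RSS is
then flat in λmax.

A caution that the synthetic studies make quantitative: identifiability
degrades when the true peak lies outside the stimulus set. With the
435–525 nm six-wavelength design, pigments near 450–490 nm are recovered
to ~1 nm, but for a 510-nm pigment all stimuli sit on one limb of the
template and the sampling SD of the estimate grows to several nm at 5%
response noise. Anyone adapting the assay to longer-wavelength pigments
should extend the stimulus set redward rather than trust the bootstrap SD
alone.

Pigment peaks measured with the commercial 9-cis retinal chromophore are
blue-shifted; `apply_chromophore_shift()` adds the 16-nm correction to
report physiological 11-cis values and refuses to correct values already
tagged 11-cis.

## Sensor calibration model

A 10-channel spectral sensor (nine narrowband channels at 415–910 nm plus
a clear channel) cannot reconstruct a full spectrum, but it can be
*calibrated per target quantity*: find weights w such that
Σᵢ wᵢ·log₁₀(countsᵢ) reproduces log₁₀(EDI) over a calibration set. The
log-domain formulation allows signed weights while guaranteeing positive
EDI predictions. Counts are normalized by gain × integration time, scaled
by 10⁶ and floored at 1 (the floor is applied after normalization — the
ordering is this package's choice). Calibration anchors (three per
spectrum) are extrapolated along the sensor's linearity to a fixed EDI
grid of −1, 0.5 and 2 log lux before fitting; the model is linear in the
weights, so the normal-equation solution is the exact least-squares
optimum and is deterministic. Predictions outside the calibrated EDI
range warn rather than refuse.

The synthetic channel model is Gaussian (FWHM 30 nm) at the nine channel
peaks plus a flat clear channel, *plus a small flat stray-light term
(5·10⁻⁴) on every narrowband channel*. The stray term is deliberate, not
cosmetic: an interference filter rejects out-of-band light imperfectly,
and that leakage is what keeps every channel responsive to every
stimulus. With idealized zero-tail channels, out-of-band channels read
exactly zero, the floor maps them to log-counts of zero, and the
log-linear model provably cannot satisfy the per-spectrum slope and
intercept constraints simultaneously — the calibration problem becomes
unlearnable in a way a real device is not. Similarly, the synthetic
device's sensitivity constant is set so that normalized counts stay at or
above 1 across the study's irradiance range, mirroring the convention
that the 10⁶ scaling keeps real counts positive and ≥ 1. On this model,
the end-to-end study (13 spectra × 3 anchors, held-out validation at 10
irradiances per spectrum over 0.2–80 W·m⁻²) yields median log absolute
errors of ~0.06–0.09 for melanopic and rhodopic EDIs in all 14 species,
and much larger S-cone errors (~0.6) for the UV-lensed rodents — the
sensor has essentially no coverage below 415 nm, so UV-weighted
quantities are only inferable from cross-spectrum correlations. That
asymmetry is a genuine property of this sensor class, not an artifact of
the simulation.

## Irradiance-response metric comparison

If a light metric captures the photoreceptor actually driving a response,
then plotting the response against that metric should collapse all
stimuli onto one sigmoid. `compare_metrics()` operationalizes this: each
narrowband stimulus is reconstructed as a Gaussian from its peak and half
width at half maximum (σ = HWHM/√(2 ln 2), the literal reading of the
HWHM specification), re-expressed in each candidate metric through the
α-opic pipeline, fitted with a 4-parameter log-logistic, and ranked by
R². R² is computed against the total sum of squares about the mean and
reported as computed — negative values are informative, not clipped.
Fits are unweighted by default with an optional 1/SEM² weighting, since
the weighting convention of published fits is rarely stated. Scale
changes of a metric are absorbed by the inflection parameter, so R² is
invariant to unit choices.

## Synthetic data: what it shows and what it cannot

Every generator is seeded and reproducible: Gaussian narrowband spectra,
three parametric broadband whites (blue-pump LED, multi-peak fluorescent,
four-primary mix — stand-ins for standard illuminant families, matched in
lux but divergent in melanopic content), log-logistic dose-response data
with multiplicative Gaussian response noise, Poisson-like sensor counts,
and a daylight series whose illuminance follows a smooth twilight-to-day
curve of solar angle (log-linear through twilight, saturating near 10⁵
lux) with a mild blue tilt at low sun. Problem sizes in the tests — 200
bootstrap replicates rather than 1000, 13 calibration spectra, ~20-point
daylight series — were chosen as the smallest sizes at which the studied
quantities stabilize.

Passing tests on these fixtures demonstrate the *pipeline*: that the
estimators recover known truths under their own generative assumptions,
that the identities hold, and that the qualitative orderings (melanopic
beats photopic for melanopsin-driven responses; UV S-cone quantities are
the sensor's weak point) emerge for the stated physical reasons. They do
not demonstrate performance on real instruments or animals: real
dose-response data have correlated plate effects and baseline drift that
multiplicative noise does not emulate; real sensor channels have
asymmetric responsivities, temperature drift and saturation; real
daylight varies in shape with weather and aerosols far beyond a tilt
parameter; and the registry's parametric lenses are class-level
stand-ins, not measured curves.

## Known limitations

- Human sensitivities are template-based approximations (see above), not
  the official tabulated functions; quantities that depend on absolute
  human sensitivity shape (rather than EDI identities) inherit that
  approximation.
- Only the A1 (11-cis retinal) template is implemented; no A2
  porphyropsin, and no Opn3/Opn5 channels.
- Adult lenses only; no age-dependent lens model.
- No colorimetry (XYZ, CCT, CRI) and no scotopic/mesopic photometry
  beyond V(λ).
- The λmax estimator assumes univariance and a single pigment; mixtures
  or bistable photopigments violate the model.
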