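Package: alphaopix
Title: Species-Specific Alpha-Opic Light Metrology for Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying light the way mammalian photoreceptors see
    it. Builds in-vivo photoreceptor spectral sensitivities from visual-pigment
    peak wavelengths (Govardovskii A1 nomogram) and ocular lens transmission,
    computes alpha-opic irradiances and equivalent daylight illuminances (EDIs)
    for a bundled registry of domestic mammal species, estimates unknown
    pigment peak wavelengths from heterologous action-spectroscopy
    dose-response data by bootstrap log-logistic fitting, calibrates a
    ten-channel multispectral light sensor to report species-specific EDIs,
    and compares candidate light metrics by irradiance-response curve fit.
    Includes seeded synthetic generators for every input class so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
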