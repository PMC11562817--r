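# Alpha-opic metrics: photoreceptor-weighted irradiance, D65 efficacy, and
# equivalent daylight illuminance (EDI), plus the bundled species registry.
#
# E_e,alpha,s   = sum_lambda E_e,lambda(lambda) s_alpha,s(lambda) dlambda
# K^D65_alpha,s = E^D65_e,alpha,s / E^D65_v
# EDI           = E_e,alpha,s / K^D65_alpha,s

.registry_cache <- new.env(parent = emptyenv())

receptor_classes <- c("s_cone", "melanopsin", "rod", "m_cone", "l_cone")

#' Alpha-opic irradiance
#'
#' Irradiance weighted by one photoreceptor's spectral sensitivity:
#' the rectangular 1-nm sum of `irradiance * weight` over the canonical
#' grid. Linear in the SPD.
#'
#' @param x An `spd` on the canonical grid.
#' @param sens A `spectral_sensitivity` on the canonical grid.
#' @return Alpha-opic irradiance in W m^-2.
#' @export
alpha_opic_irradiance <- function(x, sens) {
  x <- as_spd(x)
  stopifnot(is_sensitivity(sens))
  if (!identical(as.numeric(x$wavelength_nm), as.numeric(sens$wavelength_nm))) {
    abort("SPD and sensitivity must share the same wavelength grid.")
  }
  sum(x$irradiance * sens$weight)
}

#' Alpha-opic efficacy of luminous radiation for D65
#'
#' The conversion constant between alpha-opic irradiance and EDI: the
#' alpha-opic irradiance of the D65 daylight spectrum divided by its
#' photopic illuminance (W/lm). Independent of the absolute scaling of D65.
#'
#' @param sens A `spectral_sensitivity` on the canonical grid. Normally a
#'   lens-filtered in-vivo function; an unfiltered one is accepted.
#' @return Efficacy in W lm^-1.
#' @examples
#' d65_efficacy(photopic_sensitivity()) * 683 # = 1
#' @export
d65_efficacy <- function(sens) {
  stopifnot(is_sensitivity(sens))
  d65 <- d65_spd()
  alpha_opic_irradiance(d65, sens) / photopic_illuminance(d65)
}

build_profile <- function(name, latin_name, peaks, lens, flavor = "energy") {
  sens <- lapply(peaks, function(lm) {
    s <- govardovskii_template(lm)
    if (flavor == "energy") {
      s <- quantal_to_energy(s)
    }
    in_vivo_sensitivity(s, lens)
  })
  k_d65 <- vapply(sens, d65_efficacy, numeric(1))
  structure(
    list(
      species_name = name,
      latin_name = latin_name,
      photoreceptors = peaks,
      lens = lens,
      sensitivities = sens,
      k_d65 = k_d65,
      flavor = flavor
    ),
    class = "species_profile"
  )
}

#' Construct a species profile
#'
#' Builds lens-filtered, energy-flavored in-vivo sensitivities and their
#' D65 efficacies for a named species from per-photoreceptor pigment peak
#' wavelengths and a lens transmission curve.
#'
#' @param name Species common name.
#' @param peaks Named numeric vector of pigment lambda_max (nm); names from
#'   `s_cone`, `melanopsin`, `rod`, `m_cone`, `l_cone`. Absent classes are
#'   simply omitted.
#' @param lens A `lens_transmission`.
#' @param latin_name Optional Latin name.
#' @param flavor Sensitivity flavor used for the irradiance weighting;
#'   `"energy"` (default) or `"quantal"`.
#' @return A `species_profile` object.
#' @examples
#' p <- species_profile(
#'   "Mouse", c(melanopsin = 480, rod = 498),
#'   parametric_lens(339, 10)
#' )
#' @export
species_profile <- function(name, peaks, lens, latin_name = NA_character_,
                            flavor = c("energy", "quantal")) {
  flavor <- match.arg(flavor)
  stopifnot(is_lens(lens))
  peaks <- unlist(peaks)
  if (is.null(names(peaks)) || !all(names(peaks) %in% receptor_classes)) {
    abort(paste(
      "`peaks` must be named with photoreceptor classes:",
      paste(receptor_classes, collapse = ", ")
    ))
  }
  build_profile(name, latin_name, as.list(peaks), lens, flavor)
}

#' Load the bundled species registry
#'
#' Fourteen mammal profiles (13 non-human species plus human) with
#' per-photoreceptor pigment peak wavelengths and parametric lens models,
#' read from the packaged YAML registry. Profiles carry derived in-vivo
#' sensitivities and cached D65 efficacies.
#'
#' @param file Optional path to a user registry in the same YAML dialect;
#'   defaults to the packaged registry.
#' @param flavor Sensitivity flavor, `"energy"` (default) or `"quantal"`.
#' @return A named list of `species_profile` objects, class
#'   `species_registry`.
#' @examples
#' reg <- species_registry()
#' names(reg)
#' reg[["Mouse"]]$photoreceptors$melanopsin
#' @export
species_registry <- function(file = NULL, flavor = c("energy", "quantal")) {
  flavor <- match.arg(flavor)
  default <- is.null(file)
  key <- paste0("registry_", flavor)
  if (default && !is.null(.registry_cache[[key]])) {
    return(.registry_cache[[key]])
  }
  if (default) {
    file <- system.file("extdata", "species_registry.yaml",
      package = "alphaopix", mustWork = TRUE
    )
  }
  raw <- tryCatch(yaml::read_yaml(file), error = function(e) {
    abort(sprintf("registry file is unreadable: %s", conditionMessage(e)))
  })
  if (is.null(raw$species) || length(raw$species) == 0L) {
    abort("registry file is corrupt: no `species` entries found.")
  }
  profiles <- lapply(raw$species, function(sp) {
    if (is.null(sp$name) || is.null(sp$photoreceptors) || is.null(sp$lens)) {
      abort("registry file is corrupt: species entries need name, photoreceptors, lens.")
    }
    bad <- setdiff(names(sp$photoreceptors), receptor_classes)
    if (length(bad) > 0L) {
      abort(sprintf(
        "registry file is corrupt: unknown photoreceptor class(es) %s.",
        paste(bad, collapse = ", ")
      ))
    }
    lens <- parametric_lens(sp$lens$lambda50, sp$lens$width)
    prof <- build_profile(
      sp$name, sp$latin_name %||% NA_character_,
      sp$photoreceptors, lens, flavor
    )
    prof$is_human <- isTRUE(sp$human)
    prof
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "species_name")
  out <- structure(profiles, class = "species_registry")
  if (default) {
    .registry_cache[[key]] <- out
  }
  out
}

lookup_profile <- function(species, registry = NULL) {
  if (inherits(species, "species_profile")) {
    return(species)
  }
  registry <- registry %||% species_registry()
  if (!species %in% names(registry)) {
    abort(sprintf(
      "unknown species '%s'; available: %s.",
      species, paste(names(registry), collapse = ", ")
    ))
  }
  registry[[species]]
}

#' Alpha-opic irradiances and EDIs for a light and species
#'
#' For every photoreceptor class of the species, computes the alpha-opic
#' irradiance of the light and the equivalent daylight illuminance
#' (EDI = alpha-opic irradiance / D65 efficacy): the photopic illuminance
#' of D65 daylight that would produce the same alpha-opic irradiance.
#' Classes the species lacks are absent from the result, not zero.
#'
#' @param x An `spd` (resampled to the canonical grid if needed).
#' @param species A species name from the registry or a `species_profile`.
#' @param registry Optional registry to look names up in.
#' @return A tibble with one row per photoreceptor class: `species`,
#'   `receptor`, `lambda_max`, `alpha_opic_irradiance_W_m2`, `edi_lux`,
#'   and the scalar `photopic_lux` repeated on every row.
#' @examples
#' edi(d65_spd(target_lux = 100), "Mouse")
#' @export
edi <- function(x, species, registry = NULL) {
  x <- resample_to_canonical(as_spd(x))
  profile <- lookup_profile(species, registry)
  classes <- names(profile$sensitivities)
  irr <- vapply(
    profile$sensitivities,
    function(s) alpha_opic_irradiance(x, s),
    numeric(1)
  )
  tibble::tibble(
    species = profile$species_name,
    receptor = classes,
    lambda_max = vapply(profile$photoreceptors[classes], as.numeric, numeric(1)),
    alpha_opic_irradiance_W_m2 = unname(irr),
    edi_lux = unname(irr / profile$k_d65[classes]),
    photopic_lux = photopic_illuminance(x)
  )
}

#' Per-class summary statistics of registry pigment peaks
#'
#' Minimum, maximum, range and mean of pigment lambda_max per photoreceptor
#' class over the registry, excluding absent entries. Human is excluded by
#' default because its registry peaks are in-vivo standard-observer values
#' rather than heterologously measured pigment peaks.
#'
#' @param registry A `species_registry` (default: the bundled one).
#' @param include_human Include the human profile in the statistics?
#' @return A tibble with columns `receptor`, `n`, `min`, `max`, `range`,
#'   `mean`.
#' @examples
#' registry_summary_stats()
#' @export
registry_summary_stats <- function(registry = species_registry(),
                                   include_human = FALSE) {
  tb <- tidy(registry)
  if (!include_human) {
    tb <- dplyr::filter(tb, !.data$is_human)
  }
  tb |>
    dplyr::group_by(receptor = factor(.data$receptor, levels = receptor_classes)) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$lambda_max),
      max = max(.data$lambda_max),
      range = max(.data$lambda_max) - min(.data$lambda_max),
      mean = mean(.data$lambda_max),
      .groups = "drop"
    ) |>
    dplyr::mutate(receptor = as.character(.data$receptor))
}

#' @export
tidy.species_registry <- function(x, ...) {
  purrr::map_dfr(x, function(p) {
    tibble::tibble(
      species = p$species_name,
      latin_name = p$latin_name,
      receptor = names(p$photoreceptors),
      lambda_max = vapply(p$photoreceptors, as.numeric, numeric(1)),
      lens_lambda50 = lens_lambda50(p$lens),
      is_human = isTRUE(p$is_human)
    )
  })
}

#' @export
tidy.species_profile <- function(x, ...) {
  tibble::tibble(
    species = x$species_name,
    receptor = names(x$photoreceptors),
    lambda_max = vapply(x$photoreceptors, as.numeric, numeric(1)),
    k_d65_W_lm = unname(x$k_d65[names(x$photoreceptors)])
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf(
    "<species_profile> %s (%s): %s; lens lambda50 %.1f nm\n",
    x$species_name, x$latin_name,
    paste(sprintf("%s %g nm", names(x$photoreceptors), unlist(x$photoreceptors)),
      collapse = ", "
    ),
    lens_lambda50(x$lens)
  ))
  invisible(x)
}

#' @export
print.species_registry <- function(x, ...) {
  cat(sprintf("<species_registry> %d species:\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}
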