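#' Describe one spherical particle type
#'
#' A `particle_spec` holds the physical description needed to convert an
#' administered mass concentration into particle-number and surface-area
#' concentrations: the (monodisperse, spherical) diameter, the bulk mass
#' density, and — for particles dosed by the mass of one constituent element
#' (e.g. Cd in CdTe quantum dots) — the element mass fraction.
#'
#' @param name Particle identifier (e.g. `"QD_2.6nm"`).
#' @param diameter_nm Sphere diameter in nanometres; must be positive.
#' @param density_g_cm3 Mass density in g/cm^3; must be positive.
#' @param element_mass_fraction Fraction of particle mass contributed by the
#'   dosed element, in (0, 1]. Only relevant when `dose_basis` is
#'   `"element_mass"`; e.g. Cd in CdTe is 112.414/(112.414 + 127.60) = 0.468.
#' @param dose_basis Either `"particle_mass"` (doses are micrograms of whole
#'   particle per mL) or `"element_mass"` (doses are micrograms of the dosed
#'   element per mL, as in "ug Cd/mL").
#'
#' @return An object of class `particle_spec`.
#' @export
#' @examples
#' particle_spec("QD_4.5nm", diameter_nm = 4.5, density_g_cm3 = 5.85,
#'               element_mass_fraction = 0.468, dose_basis = "element_mass")
particle_spec <- function(name, diameter_nm, density_g_cm3,
                          element_mass_fraction = 1,
                          dose_basis = c("particle_mass", "element_mass")) {
  dose_basis <- match.arg(dose_basis)
  if (!is.numeric(diameter_nm) || length(diameter_nm) != 1 ||
      !is.finite(diameter_nm) || diameter_nm <= 0) {
    abort_validation("diameter_nm must be a single positive number",
                     field = "diameter_nm")
  }
  if (!is.numeric(density_g_cm3) || length(density_g_cm3) != 1 ||
      !is.finite(density_g_cm3) || density_g_cm3 <= 0) {
    abort_validation("density_g_cm3 must be a single positive number",
                     field = "density_g_cm3")
  }
  f <- element_mass_fraction
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f <= 0 || f > 1) {
    abort_validation(
      "element_mass_fraction must be a single number in (0, 1]",
      field = "element_mass_fraction"
    )
  }
  structure(
    list(name = as.character(name), diameter_nm = diameter_nm,
         density_g_cm3 = density_g_cm3, element_mass_fraction = f,
         dose_basis = dose_basis),
    class = "particle_spec"
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf(
    "<particle_spec> %s: d = %g nm, rho = %g g/cm^3, f = %g, dose basis = %s\n",
    x$name, x$diameter_nm, x$density_g_cm3, x$element_mass_fraction,
    x$dose_basis
  ))
  invisible(x)
}

# mass of a single spherical particle, in grams
mass_per_particle_g <- function(spec) {
  d_cm <- spec$diameter_nm / .NM_PER_CM
  spec$density_g_cm3 * (pi / 6) * d_cm^3
}

#' Convert a dose to whole-particle-mass basis
#'
#' Doses stated as mass of one element (e.g. ug Cd/mL for CdTe dots) are
#' divided by the element mass fraction so that spherical geometry applies
#' to the whole particle; particle-mass doses pass through unchanged.
#'
#' @param dose Dose(s) in ug/mL on the spec's `dose_basis`; must be >= 0.
#' @param spec A [particle_spec()].
#' @return Dose(s) in ug whole-particle mass per mL.
#' @export
to_particle_mass <- function(dose, spec) {
  stopifnot(inherits(spec, "particle_spec"))
  if (any(dose < 0, na.rm = TRUE)) {
    abort_validation("dose must be >= 0", field = "dose")
  }
  if (spec$dose_basis == "element_mass") dose / spec$element_mass_fraction
  else dose
}

#' Particle number concentration from a mass dose
#'
#' Assumes monodisperse spheres: one particle weighs rho * (pi/6) * d^3, so
#' N = (particle-mass dose in g/mL) / (rho * (pi/6) * d^3) with d in cm.
#'
#' @inheritParams to_particle_mass
#' @return Particles per mL.
#' @export
#' @examples
#' sp <- particle_spec("p", diameter_nm = 100, density_g_cm3 = 1)
#' particles_per_ml(1, sp) # 1.91e9 particles/mL
particles_per_ml <- function(dose, spec) {
  pm <- to_particle_mass(dose, spec)
  (pm / .UG_PER_G) / mass_per_particle_g(spec)
}

#' Surface-area concentration from a mass dose
#'
#' For spheres the surface-to-mass ratio is 6 / (rho * d), so
#' SA = 6 * (particle-mass dose in g/mL) / (rho * d_cm) = N * pi * d_cm^2.
#'
#' @inheritParams to_particle_mass
#' @return Surface area in cm^2 per mL.
#' @export
#' @examples
#' sp <- particle_spec("p", diameter_nm = 10, density_g_cm3 = 5)
#' surface_area_per_ml(1, sp) # 1.2 cm^2/mL
surface_area_per_ml <- function(dose, spec) {
  pm <- to_particle_mass(dose, spec)
  d_cm <- spec$diameter_nm / .NM_PER_CM
  6 * (pm / .UG_PER_G) / (spec$density_g_cm3 * d_cm)
}

#' All dosimetry conversions for a dose
#'
#' @inheritParams to_particle_mass
#' @return A tibble with columns `dose`, `mass_conc_ug_ml` (particle-mass
#'   basis), `number_per_ml`, `surface_cm2_ml`, `volume_cm3_ml`.
#' @export
convert_dose <- function(dose, spec) {
  pm <- to_particle_mass(dose, spec)
  n <- particles_per_ml(dose, spec)
  d_cm <- spec$diameter_nm / .NM_PER_CM
  tibble::tibble(
    dose = dose,
    mass_conc_ug_ml = pm,
    number_per_ml = n,
    surface_cm2_ml = n * pi * d_cm^2,
    volume_cm3_ml = n * (pi / 6) * d_cm^3
  )
}

# Mass dose (ug/mL, on the spec's dose basis) at which the administered
# amount of `metric` equals `amount`:
#   surface: amount in cm^2/mL  -> C = amount * rho * d / 6
#   volume : amount in cm^3/mL  -> C = amount * rho
#   number : amount in 1/mL     -> C = amount * mass_per_particle
#   mass   : amount in ug/mL    -> C = amount (identity, basis untouched)
mass_dose_for_metric <- function(metric, amount, spec) {
  if (any(amount < 0)) abort_validation("metric amount must be >= 0")
  d_cm <- spec$diameter_nm / .NM_PER_CM
  pm <- switch(metric,
    surface = amount * spec$density_g_cm3 * d_cm / 6 * .UG_PER_G,
    volume = amount * spec$density_g_cm3 * .UG_PER_G,
    number = amount * mass_per_particle_g(spec) * .UG_PER_G,
    mass = return(amount),
    abort_validation(paste0(
      "unknown metric '", metric,
      "'; allowed: surface, volume, number, mass"
    ), field = "metric_name")
  )
  if (spec$dose_basis == "element_mass") pm * spec$element_mass_fraction
  else pm
}

#' Read a particle metadata table
#'
#' Expects columns `name`, `diameter_nm`, `density_g_cm3`,
#' `element_mass_fraction`, `dose_basis`.
#'
#' @param path Path to a CSV file.
#' @return A named list of [particle_spec()] objects.
#' @export
read_particle_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  particle_specs_from_df(df)
}

# build named list of particle_spec from a metadata data frame
particle_specs_from_df <- function(df) {
  check_columns(df, c("name", "diameter_nm", "density_g_cm3"),
                "particle metadata table")
  if (!"element_mass_fraction" %in% names(df)) df$element_mass_fraction <- 1
  if (!"dose_basis" %in% names(df)) df$dose_basis <- "particle_mass"
  specs <- lapply(seq_len(nrow(df)), function(i) {
    particle_spec(df$name[i], df$diameter_nm[i], df$density_g_cm3[i],
                  df$element_mass_fraction[i], df$dose_basis[i])
  })
  names(specs) <- df$name
  specs
}

# inverse of particle_specs_from_df
particle_specs_to_df <- function(specs) {
  tibble::tibble(
    name = vapply(specs, `[[`, "", "name"),
    diameter_nm = vapply(specs, `[[`, 0, "diameter_nm"),
    density_g_cm3 = vapply(specs, `[[`, 0, "density_g_cm3"),
    element_mass_fraction = vapply(specs, `[[`, 0, "element_mass_fraction"),
    dose_basis = vapply(specs, `[[`, "", "dose_basis")
  )
}
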