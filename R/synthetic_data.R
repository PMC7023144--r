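#' Configure a synthetic reporter-screen panel
#'
#' Describes the generative model behind a simulated screen: each
#' (particle, reporter) cell has a true unit-slope Hill viability curve
#' `V(C) = 100 / (1 + C / LD50)` and a saturating GFP fold-induction curve
#' `fold(C) = 1 + (F_max - 1) * C / (C + D_half)`; well-level readouts get
#' multiplicative lognormal noise with mean 1 and the stated coefficient of
#' variation.
#'
#' @param particles Named list of [particle_spec()], or a data frame with
#'   the columns of the particle metadata table.
#' @param reporters Character vector of reporter line names. Default: the
#'   six ToxTracker reporters.
#' @param true_ld50s Tibble with columns `particle`, `reporter`, `ld50`
#'   (ug/mL on each particle's dose basis; `NA` marks a non-cytotoxic cell
#'   with no finite LD50), or a single number recycled to every cell.
#' @param fold_curves Tibble with columns `reporter`, `fold_max`, `d_half`
#'   (ug/mL), or `NULL` for flat curves (fold 1 everywhere: no activation).
#' @param noise_cv Coefficient of variation of the multiplicative replicate
#'   noise. Default 0.1.
#' @param n_replicates Independent replicates per well. Default 3.
#' @param control_gfp Mean vehicle-control GFP level, arbitrary
#'   fluorescence units. Default 200.
#' @param autofluorescence_per_ug Particle autofluorescence per ug/mL of
#'   dose (AU); named per particle or a single number. Default 0.
#' @param seed Integer seed governing the whole table through per-cell
#'   substreams, so regeneration is byte-identical and independent of row
#'   order.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(particles,
                         reporters = c("Srxn1", "Blvrb", "Rtkn", "Bscl2",
                                       "Ddit3", "Btg2"),
                         true_ld50s = 20,
                         fold_curves = NULL,
                         noise_cv = 0.1,
                         n_replicates = 3,
                         control_gfp = 200,
                         autofluorescence_per_ug = 0,
                         seed = 1L) {
  if (is.data.frame(particles)) particles <- particle_specs_from_df(particles)
  if (!length(particles) || !all(vapply(particles, inherits, TRUE,
                                        "particle_spec"))) {
    abort_validation("particles must be particle_spec objects",
                     field = "particles")
  }
  if (is.null(names(particles))) {
    names(particles) <- vapply(particles, `[[`, "", "name")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    abort_validation("noise_cv must be >= 0", field = "noise_cv")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort_validation("n_replicates must be >= 1", field = "n_replicates")
  }
  if (!is.numeric(control_gfp) || control_gfp <= 0) {
    abort_validation("control_gfp must be > 0", field = "control_gfp")
  }

  cells <- tidyr::expand_grid(particle = names(particles),
                              reporter = reporters)
  if (is.numeric(true_ld50s) && length(true_ld50s) == 1) {
    cells$ld50 <- true_ld50s
  } else {
    check_columns(true_ld50s, c("particle", "reporter", "ld50"),
                  "true_ld50s")
    cells <- dplyr::left_join(cells, true_ld50s,
                              by = c("particle", "reporter"))
  }
  bad <- !is.na(cells$ld50) & cells$ld50 <= 0
  if (any(bad)) {
    abort_validation(
      "true_ld50s must be > 0 or NA (non-cytotoxic)", field = "true_ld50s"
    )
  }

  if (is.null(fold_curves)) {
    fold_curves <- tibble::tibble(reporter = reporters, fold_max = 1,
                                  d_half = 1)
  }
  check_columns(fold_curves, c("reporter", "fold_max", "d_half"),
                "fold_curves")
  if (any(fold_curves$fold_max < 1) || any(fold_curves$d_half <= 0)) {
    abort_validation("fold_max must be >= 1 and d_half > 0",
                     field = "fold_curves")
  }

  if (length(autofluorescence_per_ug) == 1 &&
      is.null(names(autofluorescence_per_ug))) {
    autofluorescence_per_ug <- stats::setNames(
      rep(autofluorescence_per_ug, length(particles)), names(particles)
    )
  }

  structure(
    list(particles = particles, reporters = reporters, cells = cells,
         fold_curves = fold_curves, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates),
         control_gfp = control_gfp,
         autofluorescence_per_ug = autofluorescence_per_ug,
         seed = as.integer(seed)),
    class = "panel_config"
  )
}

# true viability / fold curves of the generative model
true_viability <- function(dose, ld50) {
  if (is.na(ld50)) rep(100, length(dose)) else 100 / (1 + dose / ld50)
}

true_fold <- function(dose, fold_max, d_half) {
  1 + (fold_max - 1) * dose / (dose + d_half)
}

# dose ladder for one cell: two-fold screening ladder up to 100 ug/mL,
# extended downward for very toxic particles, then the 50-75% rule
cell_doses <- function(ld50, max_dose = 100) {
  ladder <- max_dose / 2^(14:0)
  v <- true_viability(ladder, ld50)
  select_doses(data.frame(dose = ladder, viability = v),
               max_dose = max_dose)
}

#' Generate a synthetic reporter screen
#'
#' Emits one row per (particle, reporter, dose, replicate), including
#' vehicle-control rows at dose 0. Doses per cell follow the dose-finding
#' rule applied to the cell's noise-free viability curve (top dose at
#' 50-75% cytotoxicity, four two-fold dilutions; up to 100 ug/mL for
#' non-cytotoxic cells). Viability is the true Hill value times lognormal
#' noise, truncated to [0, 100]; GFP is the control level times the true
#' fold curve times independent lognormal noise, plus deterministic
#' particle autofluorescence proportional to dose.
#'
#' @param config A [panel_config()].
#' @return Tibble with columns `particle`, `reporter`, `dose_ug_ml`,
#'   `dose_basis`, `replicate`, `viability_pct`, `gfp_mean`,
#'   `autofluorescence`.
#' @export
#' @examples
#' cfg <- panel_config(list(particle_spec("NP", 20, 5)), reporters = "Srxn1",
#'                     true_ld50s = 10, noise_cv = 0, seed = 1)
#' generate_screen(cfg)
generate_screen <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n_rep <- config$n_replicates
  rows <- purrr::imap(config$particles, function(spec, pname) {
    i <- match(pname, names(config$particles))
    auto_slope <- config$autofluorescence_per_ug[[pname]] %||% 0
    purrr::map(seq_along(config$reporters), function(j) {
      reporter <- config$reporters[j]
      ld50 <- config$cells$ld50[config$cells$particle == pname &
                                config$cells$reporter == reporter]
      fc <- config$fold_curves[config$fold_curves$reporter == reporter, ]
      doses <- c(0, cell_doses(ld50))
      set.seed(substream_seed(config$seed, i, j))
      purrr::map_dfr(doses, function(dose) {
        v <- true_viability(dose, ld50) * rlnorm_cv(n_rep, config$noise_cv)
        g <- config$control_gfp *
          true_fold(dose, fc$fold_max, fc$d_half) *
          rlnorm_cv(n_rep, config$noise_cv)
        auto <- auto_slope * dose
        tibble::tibble(
          particle = pname, reporter = reporter, dose_ug_ml = dose,
          dose_basis = spec$dose_basis, replicate = seq_len(n_rep),
          viability_pct = pmin(100, pmax(0, v)),
          gfp_mean = g + auto, autofluorescence = auto
        )
      })
    })
  })
  dplyr::bind_rows(rows)
}

#' Define an equi-response dose-metric scenario
#'
#' Describes a particle size series in which toxicity is driven by one dose
#' metric: across all diameters, the equi-response dose corresponds to the
#' same administered amount (`ed_value`) of that metric per mL.
#'
#' @param metric_name One of `"surface"` (cm^2/mL), `"volume"` (cm^3/mL),
#'   `"number"` (particles/mL), `"mass"` (ug/mL).
#' @param ed_value The fixed per-mL amount of the metric at the
#'   equi-response point; > 0.
#' @param diameters_nm At least 3 distinct particle diameters, nm.
#' @param density_g_cm3 Common mass density, g/cm^3.
#' @param element_mass_fraction Common element mass fraction; default 1.
#' @param dose_basis Dose basis for the emitted mass doses.
#' @return A list of class `metric_scenario` with a `specs` element (one
#'   [particle_spec()] per diameter).
#' @export
metric_scenario <- function(metric_name = c("surface", "volume", "number",
                                            "mass"),
                            ed_value, diameters_nm, density_g_cm3,
                            element_mass_fraction = 1,
                            dose_basis = "particle_mass") {
  metric_name <- match.arg(metric_name)
  if (!is.numeric(ed_value) || length(ed_value) != 1 || ed_value <= 0) {
    abort_validation("ed_value must be a single positive number",
                     field = "ed_value")
  }
  if (length(unique(diameters_nm)) < 3) {
    abort_validation("at least 3 distinct diameters are required",
                     field = "diameters_nm")
  }
  specs <- lapply(diameters_nm, function(d) {
    particle_spec(paste0("d", format(d)), d, density_g_cm3,
                  element_mass_fraction, dose_basis)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(
    list(metric_name = metric_name, ed_value = ed_value,
         diameters_nm = diameters_nm, specs = specs),
    class = "metric_scenario"
  )
}

#' Generate equi-response mass doses for a size series
#'
#' For each diameter, returns the mass concentration (ug/mL on the
#' scenario's dose basis) at which the administered amount of the chosen
#' metric equals `ed_value`: proportional to rho * d for surface,
#' independent of d for volume/mass, proportional to rho * d^3 for number.
#' Optional multiplicative lognormal noise perturbs the doses, emulating
#' equi-response doses estimated from noisy viability data.
#'
#' @param scenario A [metric_scenario()].
#' @param noise_cv Coefficient of variation of lognormal noise on the mass
#'   doses. Default 0 (exact).
#' @param seed Seed used when `noise_cv > 0`.
#' @return Tibble: `particle`, `diameter_nm`, `equi_response_mass_dose`
#'   (ug/mL).
#' @export
#' @examples
#' sc <- metric_scenario("surface", ed_value = 0.5,
#'                       diameters_nm = c(10, 20, 40), density_g_cm3 = 5)
#' generate_metric_series(sc) # doses proportional to diameter
generate_metric_series <- function(scenario, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(scenario, "metric_scenario"))
  doses <- vapply(scenario$specs, function(spec) {
    mass_dose_for_metric(scenario$metric_name, scenario$ed_value, spec)
  }, 0)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    doses <- doses * rlnorm_cv(length(doses), noise_cv)
  }
  tibble::tibble(
    particle = names(scenario$specs),
    diameter_nm = scenario$diameters_nm,
    equi_response_mass_dose = unname(doses)
  )
}

#' Write a screen and its particle metadata to CSV
#'
#' @param screen Screen tibble from [generate_screen()].
#' @param config The [panel_config()] that produced it.
#' @param screen_path,particles_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_screen_csv <- function(screen, config, screen_path, particles_path) {
  readr::write_csv(screen, screen_path)
  readr::write_csv(particle_specs_to_df(config$particles), particles_path)
  invisible(c(screen_path, particles_path))
}
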