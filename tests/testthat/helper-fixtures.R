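# shared fixtures: noise-free Hill viability and small screen builders

hill_v <- function(dose, ld50) 100 / (1 + dose / ld50)

# noiseless viability series for one particle at a two-fold ladder
clean_series <- function(ld50, doses = ld50 * c(0.25, 0.5, 1, 2, 4)) {
  data.frame(dose = doses, viability = hill_v(doses, ld50))
}

# minimal screen table for one (particle, reporter) cell with explicit
# per-dose folds and viabilities (single replicate, control GFP 200)
fold_screen <- function(doses, folds, viability, particle = "NP",
                        reporter = "Srxn1", auto = 0) {
  tibble::tibble(
    particle = particle, reporter = reporter,
    dose_ug_ml = c(0, doses), dose_basis = "particle_mass",
    replicate = 1L,
    viability_pct = c(100, viability),
    gfp_mean = 200 * c(1, folds) + auto * c(0, doses),
    autofluorescence = auto * c(0, doses)
  )
}

# three-size panel config driven by a chosen dose metric: the true LD50 of
# every size corresponds to the same administered amount of that metric
metric_panel <- function(metric, diameters = c(5, 10, 20, 40, 80),
                         density = 5, noise_cv = 0.1, seed = 1) {
  specs <- lapply(diameters, function(d) {
    particle_spec(paste0("d", d), d, density)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  # pick the metric amount so mass LD50s stay well inside (0.1, 100) ug/mL
  mid <- specs[[ceiling(length(specs) / 2)]]
  ed <- ed_value_for_mid_ld50(metric, mid, target_ld50 = 10)
  ld50s <- tibble::tibble(
    particle = names(specs), reporter = "Srxn1",
    ld50 = vapply(specs, function(s) {
      nanotoxtracker:::mass_dose_for_metric(metric, ed, s)
    }, 0)
  )
  panel_config(specs, reporters = "Srxn1", true_ld50s = ld50s,
               noise_cv = noise_cv, n_replicates = 3, seed = seed)
}

# metric amount whose mass dose equals target_ld50 for the middle size
ed_value_for_mid_ld50 <- function(metric, spec, target_ld50 = 10) {
  unit_mass <- nanotoxtracker:::mass_dose_for_metric(metric, 1, spec)
  target_ld50 / unit_mass
}
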