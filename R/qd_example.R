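#' Reference CdTe quantum-dot cytotoxicity series
#'
#' A published five-size CdTe quantum-dot series with LD50 values dosed as
#' micrograms of cadmium per mL: dots of 1.5, 2.6, 4.5, 6.5 and 8.6 nm with
#' LD50s of approximately 1, 2, 4, 8.7 and 15.8 ug Cd/mL. Used as the
#' worked example for dose-metric identification: treating the LD50s as
#' equi-response doses, converting to particles/mL and regressing log10 N
#' on log10 d gives a slope near -1.44 — closest to the canonical surface
#' slope of -2, so total administered surface area best explains the
#' size-dependent toxicity.
#'
#' Density and Cd mass fraction are not part of the published series and do
#' not affect the slope (they shift only the intercept); the defaults are
#' bulk CdTe density 5.85 g/cm^3 and the stoichiometric Cd fraction
#' 112.414 / (112.414 + 127.60) = 0.4684.
#'
#' @param density_g_cm3 Assumed CdTe density. Default 5.85.
#' @param cd_mass_fraction Assumed Cd mass fraction. Default 0.46836.
#' @return A list with `series` (tibble: `particle`, `diameter_nm`,
#'   `ld50_ug_cd_ml`) and `specs` (named list of [particle_spec()]).
#' @export
#' @examples
#' qd <- cdte_qd_example()
#' n <- mapply(particles_per_ml, qd$series$ld50_ug_cd_ml, qd$specs)
#' fit_loglog(data.frame(diameter_nm = qd$series$diameter_nm,
#'                       number_per_ml = n))
cdte_qd_example <- function(density_g_cm3 = 5.85,
                            cd_mass_fraction = 112.414 / (112.414 + 127.60)) {
  series <- tibble::tibble(
    particle = paste0("QD_", c("1.5", "2.6", "4.5", "6.5", "8.6"), "nm"),
    diameter_nm = c(1.5, 2.6, 4.5, 6.5, 8.6),
    ld50_ug_cd_ml = c(1, 2, 4, 8.7, 15.8)
  )
  specs <- lapply(seq_len(nrow(series)), function(i) {
    particle_spec(series$particle[i], series$diameter_nm[i],
                  density_g_cm3, cd_mass_fraction, "element_mass")
  })
  names(specs) <- series$particle
  list(series = series, specs = specs)
}

#' Dose-metric identification for the CdTe worked example
#'
#' Converts the reference LD50s (as equi-response doses) to particle-number
#' concentrations, fits the log-log line and classifies the metric.
#'
#' @inheritParams cdte_qd_example
#' @param tolerance Passed to [classify_metric()].
#' @return A list with `fit`, `call` and `series` as in
#'   [identify_dose_metric()].
#' @export
cdte_qd_dose_metric <- function(density_g_cm3 = 5.85,
                                cd_mass_fraction =
                                  112.414 / (112.414 + 127.60),
                                tolerance = 0.75) {
  qd <- cdte_qd_example(density_g_cm3, cd_mass_fraction)
  series <- qd$series
  series$number_per_ml <- vapply(seq_len(nrow(series)), function(i) {
    particles_per_ml(series$ld50_ug_cd_ml[i], qd$specs[[i]])
  }, 0)
  fit <- fit_loglog(series)
  list(fit = fit, call = classify_metric(fit, tolerance), series = series)
}
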