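test_that("canonical scenarios give exact slopes -2, -3, 0", {
  d <- c(2, 5, 10, 20, 50)
  rho <- 5
  expected <- c(surface = -2, volume = -3, number = 0)
  for (metric in names(expected)) {
    sc <- metric_scenario(metric, ed_value = 1e-3, diameters_nm = d,
                          density_g_cm3 = rho)
    series <- generate_metric_series(sc)
    n <- vapply(seq_len(nrow(series)), function(i) {
      particles_per_ml(series$equi_response_mass_dose[i], sc$specs[[i]])
    }, 0)
    fit <- fit_loglog(data.frame(diameter_nm = d, number_per_ml = n))
    expect_equal(fit$slope_m, unname(expected[metric]), tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_identical(classify_metric(fit)$metric, metric)
  }
})

test_that("surface scenario doses scale linearly with diameter", {
  sc <- metric_scenario("surface", ed_value = 0.5,
                        diameters_nm = c(10, 20, 40), density_g_cm3 = 5)
  ser <- generate_metric_series(sc)
  # C = ed * rho * d / 6 (unit-converted): 20 nm needs exactly 2x the 10 nm dose
  expect_equal(ser$equi_response_mass_dose[2] /
                 ser$equi_response_mass_dose[1], 2, tolerance = 1e-12)
  expect_equal(ser$equi_response_mass_dose[1],
               0.5 * 5 * (10 / 1e7) / 6 * 1e6, tolerance = 1e-12)
})

test_that("volume scenario doses are size-independent; number doses keep N fixed", {
  d <- c(5, 15, 45)
  vol <- generate_metric_series(
    metric_scenario("volume", 1e-6, d, density_g_cm3 = 3)
  )
  expect_equal(diff(range(vol$equi_response_mass_dose)), 0, tolerance = 1e-15)
  sc_n <- metric_scenario("number", 1e10, d, density_g_cm3 = 3)
  ser_n <- generate_metric_series(sc_n)
  n_back <- vapply(seq_len(3), function(i) {
    particles_per_ml(ser_n$equi_response_mass_dose[i], sc_n$specs[[i]])
  }, 0)
  expect_equal(n_back, rep(1e10, 3), tolerance = 1e-12)
})

test_that("fit_loglog validates its inputs", {
  expect_error(
    fit_loglog(data.frame(diameter_nm = c(1, 2), number_per_ml = c(1, 2))),
    class = "ntx_insufficient_data_error"
  )
  expect_error(
    fit_loglog(data.frame(diameter_nm = c(1, 2, 3),
                          number_per_ml = c(1, 0, 2))),
    class = "ntx_validation_error"
  )
})

test_that("classifier picks the nearest canonical slope within tolerance", {
  mk <- function(m) {
    d <- c(2, 6, 18)
    fit_loglog(data.frame(diameter_nm = d, number_per_ml = 1e10 * d^m))
  }
  expect_identical(classify_metric(mk(-1.44))$metric, "surface")
  expect_identical(classify_metric(mk(-1.7))$metric, "surface")
  expect_identical(classify_metric(mk(-3))$metric, "volume")
  expect_identical(classify_metric(mk(-2.9))$metric, "volume")
  expect_identical(classify_metric(mk(0.1))$metric, "number")
  # outside tolerance: -0.8 is 0.8 from number at the default 0.75
  expect_identical(classify_metric(mk(-0.8))$metric, "intermediate")
})

test_that("equidistant slopes classify as intermediate with Eq-2 quantities", {
  d <- c(2, 6, 18, 54)
  # N * d^2.5 held fixed: slope exactly -2.5, equidistant from -2 and -3
  fit <- fit_loglog(data.frame(diameter_nm = d, number_per_ml = 1e12 / d^2.5))
  call <- classify_metric(fit)
  expect_identical(call$metric, "intermediate")
  expect_equal(call$intermediate_exponent, 2.5, tolerance = 1e-9)
  # the intermediate metric N * d^-m is constant across sizes: 10^q
  n_dm <- (1e12 / d^2.5) * d^(-fit$slope_m)
  expect_equal(n_dm / call$intermediate_constant, rep(1, 4),
               tolerance = 1e-9)
})

test_that("slope is invariant to the assumed density and mass fraction", {
  qd1 <- cdte_qd_dose_metric(density_g_cm3 = 5.85)
  qd2 <- cdte_qd_dose_metric(density_g_cm3 = 11.7)
  qd3 <- cdte_qd_dose_metric(cd_mass_fraction = 0.9)
  expect_equal(qd1$fit$slope_m, qd2$fit$slope_m, tolerance = 1e-12)
  expect_equal(qd1$fit$slope_m, qd3$fit$slope_m, tolerance = 1e-12)
  # only the intercept moves: doubling rho halves N at every size
  expect_equal(qd2$fit$intercept_q - qd1$fit$intercept_q, log10(0.5),
               tolerance = 1e-9)
})

test_that("intermediate-exponent series round-trip through fit and Eq 2", {
  set.seed(11)
  for (p in c(0.7, 1.9, 2.6)) {
    d <- sort(10^runif(5, 0.3, 2))
    n <- 10^6.5 / d^p
    fit <- fit_loglog(data.frame(diameter_nm = d, number_per_ml = n))
    expect_equal(-fit$slope_m, p, tolerance = 1e-9)
    expect_equal(n * d^(-fit$slope_m) / 10^fit$intercept_q, rep(1, 5),
                 tolerance = 1e-9)
  }
})

test_that("metric overlay collapses size series driven by that metric", {
  d <- c(5, 10, 20, 40, 80)
  cfg <- metric_panel("surface", diameters = d, noise_cv = 0, seed = 5)
  screen <- generate_screen(cfg)
  overlay <- metric_overlay_table(screen, cfg$particles, "surface")
  # at equal surface dose the noise-free viabilities coincide across sizes
  one_rep <- overlay[overlay$dose_ug_ml > 0 & overlay$replicate == 1, ]
  key <- dplyr::summarise(
    dplyr::group_by(one_rep, particle),
    v_at = stats::approx(metric_dose, viability_pct, xout = 2, rule = 1)$y,
    .groups = "drop"
  )
  expect_true(all(is.finite(key$v_at)))
  expect_lt(diff(range(key$v_at)), 1e-6)
  # identity conversion for the mass metric
  id <- metric_overlay_table(screen, cfg$particles, "mass")
  expect_identical(id$metric_dose, screen$dose_ug_ml)
  # number-driven series separate monotonically on the surface axis:
  # larger particles need more surface area for the same response
  d_n <- c(10, 17, 30)
  cfg_n <- metric_panel("number", diameters = d_n, noise_cv = 0, seed = 5)
  ov_n <- metric_overlay_table(generate_screen(cfg_n), cfg_n$particles,
                               "surface")
  sa50 <- vapply(paste0("d", d_n), function(p) {
    sub <- ov_n[ov_n$particle == p & ov_n$dose_ug_ml > 0 &
                  ov_n$replicate == 1, ]
    stats::approx(sub$viability_pct, sub$metric_dose, xout = 50)$y
  }, 0)
  expect_true(all(is.finite(sa50)))
  expect_true(all(diff(sa50) > 0))
  expect_error(
    metric_overlay_table(screen, cfg$particles[-1], "surface"),
    class = "ntx_schema_error"
  )
})

test_that("end-to-end metric recovery works from Hill fits", {
  cfg <- metric_panel("surface", noise_cv = 0, seed = 9)
  fits <- fit_hill_table(generate_screen(cfg))
  id <- identify_dose_metric(fits, cfg$particles)
  expect_identical(id$call$metric, "surface")
  expect_equal(id$fit$slope_m, -2, tolerance = 1e-6)
})

test_that("reference CdTe series is classified as surface-driven", {
  qd <- cdte_qd_dose_metric()
  expect_gte(qd$fit$slope_m, -1.7)
  expect_lte(qd$fit$slope_m, -1.4)
  expect_identical(qd$call$metric, "surface")
  expect_identical(qd$call$canonical_slope, -2)
})
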