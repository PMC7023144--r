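# Canonical log-log slopes: at equi-response doses held at a fixed total
# surface area the particle number scales as d^-2, at fixed total volume as
# d^-3, and at fixed particle number as d^0.
canonical_slopes <- c(surface = -2, volume = -3, number = 0)

#' Fit the equi-response log-log line
#'
#' Ordinary least-squares line through (log10 diameter, log10 particle
#' number) across a particle size series at equi-response doses. The slope
#' identifies the dose metric driving toxicity: -2 for surface area, -3 for
#' volume (equivalently mass at fixed density), 0 for particle number.
#'
#' @param series Data frame with columns `diameter_nm` (> 0) and
#'   `number_per_ml` (> 0): one equi-response particle-number concentration
#'   per particle size.
#' @return An object of class `dose_metric_fit`: `slope_m`, `intercept_q`
#'   (log10 particles/mL at log10 d = 0, d in nm), `r_squared`, `n_sizes`.
#' @export
#' @examples
#' d <- c(2, 5, 10, 20, 50)
#' # fixed total surface area: N proportional to d^-2
#' fit_loglog(data.frame(diameter_nm = d, number_per_ml = 1e12 / d^2))$slope_m
fit_loglog <- function(series) {
  check_columns(series, c("diameter_nm", "number_per_ml"),
                "equi-response series")
  d <- series$diameter_nm
  n <- series$number_per_ml
  if (length(unique(d)) < 3) {
    abort_insufficient(
      "at least 3 distinct diameters are required to identify a dose metric"
    )
  }
  if (any(d <= 0) || any(n <= 0)) {
    abort_validation(
      "diameters and particle numbers must be strictly positive (log scale)"
    )
  }
  fit <- stats::lm(log10(n) ~ log10(d))
  res <- stats::residuals(fit)
  tss <- sum((log10(n) - mean(log10(n)))^2)
  rss <- sum(res^2)
  # a perfectly flat, perfectly fitted line (number metric) has tss = 0
  r2 <- if (tss < 1e-24) {
    if (rss < 1e-18) 1 else 0
  } else {
    1 - rss / tss
  }
  structure(
    list(
      slope_m = unname(stats::coef(fit)[2]),
      intercept_q = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n_sizes = length(d)
    ),
    class = "dose_metric_fit"
  )
}

#' @export
print.dose_metric_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_metric_fit> log10(N) = %.4g * log10(d) + %.4g (r^2 = %.4f, %d sizes)\n",
    x$slope_m, x$intercept_q, x$r_squared, x$n_sizes
  ))
  invisible(x)
}

#' Classify the dose metric from a fitted log-log slope
#'
#' Picks the canonical metric (surface -2, volume -3, number 0) whose slope
#' is strictly nearest to the fitted slope, provided it lies within
#' `tolerance`; otherwise — including exact ties between two canonical
#' slopes — reports an intermediate metric characterised by the quantity
#' `N * d^-m = 10^q`, which is constant across sizes when the line fits.
#'
#' @param fit A [fit_loglog()] result.
#' @param tolerance Maximum |slope - canonical| for a canonical call.
#'   Default 0.75: inside half the unit gap between canonical slopes, so a
#'   slope must be clearly nearest one metric to be named after it.
#' @return A list of class `dose_metric_call`: `metric` (one of `"surface"`,
#'   `"volume"`, `"number"`, `"intermediate"`), `canonical_slope` (NA when
#'   intermediate), `slope_m`, `intercept_q`, `intermediate_exponent` (-m,
#'   populated when intermediate), `intermediate_constant` (10^q), and the
#'   `tolerance` used.
#' @export
#' @examples
#' fit <- fit_loglog(data.frame(diameter_nm = c(2, 5, 10),
#'                              number_per_ml = 1e12 / c(2, 5, 10)^2))
#' classify_metric(fit)$metric # "surface"
classify_metric <- function(fit, tolerance = 0.75) {
  stopifnot(inherits(fit, "dose_metric_fit"))
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance <= 0) {
    abort_validation("tolerance must be a single positive number",
                     field = "tolerance")
  }
  m <- fit$slope_m
  dist <- abs(m - canonical_slopes)
  # distances equal to within 1e-9 count as an exact tie, so floating-point
  # error in a fitted slope of exactly -2.5 cannot silently break it
  nearest <- which(dist <= min(dist) + 1e-9)
  intermediate <- length(nearest) > 1 || dist[nearest] > tolerance
  structure(
    list(
      metric = if (intermediate) "intermediate"
               else names(canonical_slopes)[nearest],
      canonical_slope = if (intermediate) NA_real_
                        else unname(canonical_slopes[nearest]),
      slope_m = m,
      intercept_q = fit$intercept_q,
      intermediate_exponent = if (intermediate) -m else NA_real_,
      intermediate_constant = if (intermediate) 10^fit$intercept_q
                              else NA_real_,
      tolerance = tolerance
    ),
    class = "dose_metric_call"
  )
}

#' @export
print.dose_metric_call <- function(x, ...) {
  if (x$metric == "intermediate") {
    cat(sprintf(
      "<dose_metric_call> intermediate metric: N * d^-%.3g = %.4g (slope %.3g)\n",
      -x$intermediate_exponent, x$intermediate_constant, x$slope_m
    ))
  } else {
    cat(sprintf(
      "<dose_metric_call> %s (canonical slope %g; fitted %.3g, tolerance %g)\n",
      x$metric, x$canonical_slope, x$slope_m, x$tolerance
    ))
  }
  invisible(x)
}

#' Re-express screen doses in a chosen dose metric
#'
#' Adds a `metric_dose` column to a screen table: the administered amount of
#' the chosen metric at each row's mass dose (surface cm^2/mL, volume
#' cm^3/mL, number particles/mL; mass leaves the dose column unchanged).
#' When the metric truly drives toxicity, per-size viability curves overlap
#' on this axis.
#'
#' @param screen Screen table with columns `particle`, `dose_ug_ml`.
#' @param specs Named list of [particle_spec()] covering every particle.
#' @param metric One of `"surface"`, `"volume"`, `"number"`, `"mass"`.
#' @return The screen tibble with added columns `metric` and `metric_dose`.
#' @export
metric_overlay_table <- function(screen, specs,
                                 metric = c("surface", "volume", "number",
                                            "mass")) {
  metric <- match.arg(metric)
  check_columns(screen, c("particle", "dose_ug_ml"), "screen table")
  missing <- setdiff(unique(screen$particle), names(specs))
  if (length(missing) > 0) {
    abort_schema(paste0("no particle spec for: ",
                        paste(missing, collapse = ", ")),
                 missing = missing)
  }
  out <- tibble::as_tibble(screen)
  out$metric <- metric
  out$metric_dose <- purrr::map2_dbl(
    out$particle, out$dose_ug_ml,
    function(p, dose) {
      if (metric == "mass") return(dose)
      conv <- convert_dose(dose, specs[[p]])
      switch(metric,
             surface = conv$surface_cm2_ml,
             volume = conv$volume_cm3_ml,
             number = conv$number_per_ml)
    }
  )
  out
}

#' Identify the dose metric for a size series from Hill fits
#'
#' Convenience wrapper for the full identification step: takes per-size
#' non-censored Hill fits, computes the equi-response dose at `level`%
#' viability decrease for each size, converts it to particles/mL, fits the
#' log-log line and classifies the metric.
#'
#' @param fits Tibble from [fit_hill_table()] (or same columns), one row per
#'   particle for a single reporter line.
#' @param specs Named list of [particle_spec()].
#' @param level Equi-response level: percent viability decrease. Default 20.
#' @param tolerance Passed to [classify_metric()].
#' @return A list with `fit` ([fit_loglog()] result), `call`
#'   ([classify_metric()] result) and `series` (the per-size equi-response
#'   table).
#' @export
identify_dose_metric <- function(fits, specs, level = 20, tolerance = 0.75) {
  check_columns(fits, c("particle", "ld50", "censored"), "fit table")
  usable <- fits[!fits$censored, , drop = FALSE]
  if (nrow(usable) < 3) {
    abort_insufficient(paste0(
      "dose-metric identification needs >= 3 non-censored fits; got ",
      nrow(usable)
    ))
  }
  series <- purrr::pmap_dfr(
    usable[, c("particle", "ld50")],
    function(particle, ld50) {
      spec <- specs[[particle]]
      if (is.null(spec)) {
        abort_schema(paste0("no particle spec for: ", particle),
                     missing = particle)
      }
      ed <- ld50 * level / (100 - level)
      tibble::tibble(
        particle = particle, diameter_nm = spec$diameter_nm,
        equi_response_dose = ed,
        number_per_ml = particles_per_ml(ed, spec)
      )
    }
  )
  fit <- fit_loglog(series)
  list(fit = fit, call = classify_metric(fit, tolerance), series = series)
}
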