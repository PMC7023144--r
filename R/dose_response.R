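#' Fit the fixed-slope Hill cytotoxicity model
#'
#' Fits `V(C) = 100 / (1 + C / LD50)` — a Hill curve with slope fixed at 1,
#' anchored at 100% viability at dose 0 — to viability-versus-dose data by
#' ordinary least squares, optimised over log(LD50) so the estimate is
#' positive by construction. Vehicle-control rows (dose 0) are excluded:
#' the model passes through 100% at zero dose by construction.
#'
#' The fit is reported as censored (no finite LD50 supported by the data)
#' when the mean viability at the top tested dose exceeds
#' `censor_viability` or the fitted LD50 exceeds `censor_factor` times the
#' top tested dose; such particles are reported as "LD50 > max dose" rather
#' than extrapolated.
#'
#' @param data A data frame with columns `dose` (ug/mL) and `viability`
#'   (percent of vehicle control, in `[0, 100]` up to noise overshoot).
#' @param censor_viability Mean top-dose viability (%) above which the fit
#'   is censored. Default 75.
#' @param censor_factor Multiple of the top tested dose beyond which a
#'   fitted LD50 is treated as unsupported. Default 2.
#' @return An object of class `hill_fit` with fields `ld50`, `censored`,
#'   `max_dose_tested`, `rss`, `n_points` and, when censored, `bound`
#'   (the reported lower bound on LD50).
#' @export
#' @examples
#' d <- c(2.5, 5, 10, 20, 40)
#' fit <- fit_hill_ld50(data.frame(dose = d, viability = 100 / (1 + d / 10)))
#' fit$ld50 # 10
fit_hill_ld50 <- function(data, censor_viability = 75, censor_factor = 2) {
  check_columns(data, c("dose", "viability"), "viability series")
  data <- data[data$dose > 0, , drop = FALSE]
  doses <- data$dose
  v <- data$viability
  if (length(unique(doses)) < 3) {
    abort_insufficient(
      "at least 3 distinct non-zero doses are required to fit the Hill model"
    )
  }
  if (any(!is.finite(v)) || any(v < 0) || any(v > 110)) {
    abort_validation("viability must be finite and within [0, 110]%",
                     field = "viability")
  }
  if (all(v < 1e-8)) {
    abort_degenerate(paste0(
      "viability is zero at every dose; the dose range is entirely ",
      "cytotoxic - repeat the screen at lower doses"
    ))
  }

  max_dose <- max(doses)
  sse <- function(log_l) {
    pred <- 100 / (1 + doses / exp(log_l))
    sum((v - pred)^2)
  }
  # 1-D profile over log(LD50); generous bracket around the tested range,
  # then a gradient root-finding polish (golden-section alone stalls near
  # 1e-8 relative)
  lo <- log(min(doses)) - log(1e8)
  hi <- log(max_dose) + log(1e8)
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  grad <- function(log_l) {
    ratio <- doses / exp(log_l)
    pred <- 100 / (1 + ratio)
    sum(2 * (pred - v) * 100 * ratio / (1 + ratio)^2)
  }
  root <- tryCatch(
    stats::uniroot(grad, opt$minimum + c(-0.5, 0.5), tol = 1e-14),
    error = function(e) NULL
  )
  best <- opt$minimum
  if (!is.null(root) && sse(root$root) <= opt$objective) best <- root$root
  ld50 <- exp(best)
  rss <- sse(best)

  top_mean_v <- mean(v[doses == max_dose])
  censored <- top_mean_v > censor_viability || ld50 > censor_factor * max_dose

  structure(
    list(
      ld50 = if (censored) NA_real_ else ld50,
      censored = censored,
      bound = if (censored) max_dose else NA_real_,
      max_dose_tested = max_dose,
      rss = rss,
      n_points = length(v)
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<hill_fit> censored: LD50 > %g ug/mL (top dose tested)\n",
                x$bound))
  } else {
    cat(sprintf("<hill_fit> LD50 = %.4g ug/mL (unit Hill slope)\n", x$ld50))
  }
  cat(sprintf("  n = %d points, RSS = %.4g, max dose = %g ug/mL\n",
              x$n_points, x$rss, x$max_dose_tested))
  invisible(x)
}

#' Predicted viability under a fitted Hill curve
#'
#' @param fit A non-censored [fit_hill_ld50()] result.
#' @param dose Dose(s), ug/mL.
#' @return Predicted viability (%).
#' @export
predict_viability <- function(fit, dose) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$censored) {
    abort_validation("cannot predict from a censored fit: no finite LD50")
  }
  100 / (1 + dose / fit$ld50)
}

#' Equi-response dose from a Hill fit
#'
#' Inverts the unit-slope Hill curve analytically: the dose producing an
#' `x`% decrease in viability (viability `100 - x`) is
#' `LD50 * x / (100 - x)`. At `x = 50` this is the LD50 itself; at `x = 20`
#' (the usual equi-response level for dose-metric work) it is LD50 / 4.
#'
#' @param fit A non-censored [fit_hill_ld50()] result.
#' @param x Response level: percent decrease in viability, in (0, 100).
#' @return A list of class `equi_response_dose` with `response_level_x`,
#'   `dose` (ug/mL, same basis as the fitted doses) and `source_fit`.
#' @export
#' @examples
#' fit <- fit_hill_ld50(data.frame(
#'   dose = c(2, 8, 32), viability = 100 / (1 + c(2, 8, 32) / 8)))
#' equi_response_dose(fit, 20)$dose # 2
equi_response_dose <- function(fit, x = 20) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$censored) {
    abort_validation(paste0(
      "equi-response dose is undefined for a censored fit: the response ",
      "level was not reached within the tested dose range (LD50 > ",
      fit$bound, ")"
    ))
  }
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 100) {
    abort_validation("response level x must be in (0, 100)", field = "x")
  }
  structure(
    list(response_level_x = x, dose = fit$ld50 * x / (100 - x),
         source_fit = fit),
    class = "equi_response_dose"
  )
}

#' @export
print.equi_response_dose <- function(x, ...) {
  cat(sprintf("<equi_response_dose> ED%g = %.4g ug/mL (LD50 = %.4g)\n",
              x$response_level_x, x$dose, x$source_fit$ld50))
  invisible(x)
}

#' Fit Hill LD50s for every (particle, reporter) cell of a screen
#'
#' @param screen Long-format screen table with columns `particle`,
#'   `reporter`, `dose_ug_ml`, `viability_pct`.
#' @param ... Passed to [fit_hill_ld50()].
#' @return A tibble with one row per (particle, reporter): `ld50`,
#'   `censored`, `bound`, `rss`, `n_points`.
#' @export
fit_hill_table <- function(screen, ...) {
  check_columns(screen, c("particle", "reporter", "dose_ug_ml",
                          "viability_pct"), "screen table")
  cells <- dplyr::distinct(screen, .data$particle, .data$reporter)
  purrr::pmap_dfr(cells, function(particle, reporter) {
    sub <- screen[screen$particle == particle & screen$reporter == reporter, ]
    fit <- fit_hill_ld50(
      data.frame(dose = sub$dose_ug_ml, viability = sub$viability_pct), ...
    )
    tibble::tibble(
      particle = particle, reporter = reporter,
      ld50 = fit$ld50, censored = fit$censored, bound = fit$bound,
      rss = fit$rss, n_points = fit$n_points
    )
  })
}
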