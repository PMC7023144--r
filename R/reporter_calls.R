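#' Subtract particle autofluorescence from reporter GFP signal
#'
#' Some particles (notably CdTe quantum dots) fluoresce in the GFP channel;
#' their intrinsic signal, measured in non-modified cells, is subtracted
#' from the reporter readout before fold induction is computed. The
#' corrected value is floored at zero — a warning is raised when the floor
#' is applied, since it means the particle signal exceeded the reporter
#' signal.
#'
#' @param gfp_mean Mean GFP fluorescence of the reporter cells (>= 0).
#' @param autofluorescence_mean Particle-only fluorescence at the same dose
#'   (>= 0); scalar or same length as `gfp_mean`.
#' @return Corrected GFP, `max(gfp - autofluorescence, 0)`.
#' @export
correct_autofluorescence <- function(gfp_mean, autofluorescence_mean) {
  if (length(autofluorescence_mean) != 1 &&
      length(autofluorescence_mean) != length(gfp_mean)) {
    rlang::abort(
      "autofluorescence values do not align with GFP values (length mismatch)",
      class = "ntx_alignment_error"
    )
  }
  if (any(gfp_mean < 0) || any(autofluorescence_mean < 0)) {
    abort_validation("fluorescence values must be >= 0")
  }
  corrected <- gfp_mean - autofluorescence_mean
  if (any(corrected < 0)) {
    rlang::warn(paste0(
      sum(corrected < 0),
      " well(s) had autofluorescence exceeding the GFP signal; ",
      "corrected values floored at 0"
    ), class = "ntx_floor_warning")
  }
  pmax(corrected, 0)
}

#' GFP fold induction relative to vehicle control
#'
#' Ratio of replicate means: mean corrected GFP at the dose divided by mean
#' corrected GFP of the vehicle control. Replicates are averaged first,
#' then the ratio is taken.
#'
#' @param gfp_dose Corrected GFP replicate values at the dose.
#' @param gfp_control Corrected GFP replicate values of the vehicle control.
#' @return Fold induction (dimensionless).
#' @export
#' @examples
#' fold_induction(c(680, 720), c(195, 205)) # 3.5
fold_induction <- function(gfp_dose, gfp_control) {
  ctrl <- mean(gfp_control)
  if (!is.finite(ctrl) || ctrl <= 0) {
    abort_degenerate(
      "vehicle-control GFP is not positive; fold induction undefined"
    )
  }
  mean(gfp_dose) / ctrl
}

#' Per-dose fold induction table for a screen
#'
#' For each (particle, reporter, dose): subtracts autofluorescence per well,
#' averages replicates, and divides by the vehicle-control mean of the same
#' (particle, reporter) cell. Vehicle-control rows get fold 1 by
#' construction.
#'
#' @param screen Long-format screen table with columns `particle`,
#'   `reporter`, `dose_ug_ml`, `viability_pct`, `gfp_mean` and optionally
#'   `autofluorescence` (taken as 0 when absent).
#' @param viability_gate Viability (%) at or below which a dose is flagged
#'   `gated_out`. Default 25.
#' @return Tibble: `particle`, `reporter`, `dose_ug_ml`, `fold`,
#'   `viability_pct` (replicate mean), `gated_out`.
#' @export
fold_table <- function(screen, viability_gate = 25) {
  check_columns(screen, c("particle", "reporter", "dose_ug_ml",
                          "viability_pct", "gfp_mean"), "screen table")
  auto <- if ("autofluorescence" %in% names(screen)) {
    screen$autofluorescence
  } else {
    rep(0, nrow(screen))
  }
  screen$corrected_gfp <- correct_autofluorescence(screen$gfp_mean, auto)
  per_dose <- screen |>
    dplyr::group_by(.data$particle, .data$reporter, .data$dose_ug_ml) |>
    dplyr::summarise(
      mean_gfp = mean(.data$corrected_gfp),
      viability_pct = mean(.data$viability_pct),
      .groups = "drop_last"
    )
  out <- per_dose |>
    dplyr::mutate(
      control_gfp = {
        ctrl <- .data$mean_gfp[.data$dose_ug_ml == 0]
        if (length(ctrl) != 1 || !is.finite(ctrl) || ctrl <= 0) {
          abort_degenerate(paste0(
            "missing or non-positive vehicle control (dose 0) for ",
            dplyr::cur_group()$particle, " / ", dplyr::cur_group()$reporter
          ))
        }
        ctrl
      },
      fold = .data$mean_gfp / .data$control_gfp
    ) |>
    dplyr::ungroup()
  out$gated_out <- out$viability_pct <= viability_gate
  out[, c("particle", "reporter", "dose_ug_ml", "fold", "viability_pct",
          "gated_out")]
}

#' Call reporter activation from a fold-induction series
#'
#' Applies the ToxTracker decision rule to one (particle, reporter) cell:
#' doses at viability <= `viability_gate`% are excluded (cytotoxicity
#' artefact gate); the verdict comes from the maximum fold among the
#' remaining doses — `positive` above `positive_threshold` (strictly),
#' `weak_positive` above `weak_threshold` up to and including
#' `positive_threshold`, else `negative`. A fold of exactly 2 therefore
#' counts as weak positive, keeping the bands exhaustive. If every dose is
#' gated out the cell is `uninterpretable`.
#'
#' @param folds Tibble for one (particle, reporter): columns `dose_ug_ml`,
#'   `fold`, `viability_pct` (vehicle-control rows, dose 0, are ignored).
#' @param positive_threshold Fold above which (strictly) a call is positive.
#'   Default 2.
#' @param weak_threshold Fold above which (strictly) a call is at least weak
#'   positive. Default 1.5.
#' @param viability_gate Viability (%) at or below which a dose is excluded.
#'   Default 25.
#' @return A list of class `reporter_call`: `verdict` (`"negative"`,
#'   `"weak_positive"`, `"positive"`, `"uninterpretable"`),
#'   `max_valid_fold`, `lowest_positive_dose` (NA when none),
#'   `gated_doses`.
#' @export
call_reporter <- function(folds, positive_threshold = 2,
                          weak_threshold = 1.5, viability_gate = 25) {
  check_columns(folds, c("dose_ug_ml", "fold", "viability_pct"),
                "fold table")
  folds <- folds[folds$dose_ug_ml > 0, , drop = FALSE]
  if (nrow(folds) == 0) {
    abort_insufficient("at least one non-control dose is required")
  }
  valid <- folds$viability_pct > viability_gate
  gated_doses <- folds$dose_ug_ml[!valid]
  if (!any(valid)) {
    return(structure(
      list(verdict = "uninterpretable", max_valid_fold = NA_real_,
           lowest_positive_dose = NA_real_, gated_doses = gated_doses,
           explanation = paste0(
             "all doses showed viability <= ", viability_gate,
             "%; activation cannot be distinguished from cytotoxicity"
           )),
      class = "reporter_call"
    ))
  }
  max_valid_fold <- max(folds$fold[valid])
  verdict <- if (max_valid_fold > positive_threshold) "positive"
             else if (max_valid_fold > weak_threshold) "weak_positive"
             else "negative"
  pos_doses <- folds$dose_ug_ml[valid & folds$fold > positive_threshold]
  structure(
    list(
      verdict = verdict,
      max_valid_fold = max_valid_fold,
      lowest_positive_dose = if (length(pos_doses)) min(pos_doses)
                             else NA_real_,
      gated_doses = gated_doses,
      explanation = NULL
    ),
    class = "reporter_call"
  )
}

#' @export
print.reporter_call <- function(x, ...) {
  cat(sprintf("<reporter_call> %s (max valid fold %.3g)\n",
              x$verdict, x$max_valid_fold))
  if (length(x$gated_doses)) {
    cat("  gated doses (viability at/below gate):",
        paste(signif(x$gated_doses, 4), collapse = ", "), "\n")
  }
  if (!is.null(x$explanation)) cat(" ", x$explanation, "\n")
  invisible(x)
}

#' Call every (particle, reporter) cell of a screen
#'
#' @param screen Long-format screen table (see [fold_table()]).
#' @inheritParams call_reporter
#' @return Tibble: `particle`, `reporter`, `verdict`, `max_valid_fold`,
#'   `lowest_positive_dose`, `gated_doses` (comma-separated).
#' @export
call_reporter_table <- function(screen, positive_threshold = 2,
                                weak_threshold = 1.5, viability_gate = 25) {
  folds <- fold_table(screen, viability_gate = viability_gate)
  cells <- dplyr::distinct(folds, .data$particle, .data$reporter)
  purrr::pmap_dfr(cells, function(particle, reporter) {
    sub <- folds[folds$particle == particle & folds$reporter == reporter, ]
    call <- call_reporter(sub, positive_threshold, weak_threshold,
                          viability_gate)
    tibble::tibble(
      particle = particle, reporter = reporter,
      verdict = call$verdict, max_valid_fold = call$max_valid_fold,
      lowest_positive_dose = call$lowest_positive_dose,
      gated_doses = paste(signif(call$gated_doses, 6), collapse = ";")
    )
  })
}

#' Select the reporter-assay dose ladder from a cytotoxicity screen
#'
#' Implements the dose-finding rule used before reporter analysis: the top
#' dose is the smallest tested dose causing 50-75% cytotoxicity
#' (cytotoxicity = 100 - viability); four further doses follow in two-fold
#' dilution steps. When no tested dose reaches 50% cytotoxicity the
#' particle is treated as non-cytotoxic and tested up to `max_dose`
#' (default 100 ug/mL). When cytotoxicity jumps over the 50-75% band, the
#' largest tested dose still under 50% cytotoxicity is used. If even the
#' lowest tested dose exceeds 75% cytotoxicity no ladder exists and an
#' error advises re-screening at lower doses.
#'
#' @param screen Data frame with columns `dose` and `viability` (replicates
#'   allowed; dose 0 rows ignored).
#' @param max_dose Cap for non-cytotoxic particles. Default 100.
#' @return Numeric vector of 5 doses, ascending (`top/16 ... top`).
#' @export
#' @examples
#' sc <- data.frame(dose = c(10, 20, 40, 80),
#'                  viability = c(80, 65, 40, 15))
#' select_doses(sc) # 40 ug/mL gives 60% cytotoxicity -> 2.5 5 10 20 40
select_doses <- function(screen, max_dose = 100) {
  check_columns(screen, c("dose", "viability"), "cytotoxicity screen")
  screen <- screen[screen$dose > 0, , drop = FALSE]
  if (length(unique(screen$dose)) < 4) {
    abort_insufficient(
      "the cytotoxicity screen must span at least 4 non-zero doses"
    )
  }
  per_dose <- stats::aggregate(viability ~ dose, data = screen, FUN = mean)
  per_dose <- per_dose[order(per_dose$dose), ]
  cyto <- 100 - per_dose$viability
  in_band <- cyto >= 50 & cyto <= 75
  if (any(in_band)) {
    top <- min(per_dose$dose[in_band])
  } else if (max(cyto) < 50) {
    top <- max_dose
  } else if (all(cyto > 75)) {
    abort_degenerate(paste0(
      "every tested dose exceeds 75% cytotoxicity; ",
      "repeat the screen at a lower dose range"
    ))
  } else {
    top <- max(per_dose$dose[cyto < 50])
  }
  top / 2^(4:0)
}
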